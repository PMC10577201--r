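## COCO-dialect readers/writers. On disk: images + annotations with
## [x, y, w, h] boxes + categories; internally boxes are (x1, y1, x2, y2)
## with x2 = x + w, y2 = y + h. The unknown sentinel is a dedicated category
## record named "unknown" with the reserved id -1.

#' Read ground truth from a COCO-dialect JSON file
#'
#' Every annotation's \code{[x, y, w, h]} is converted to an
#' \code{(x1, y1, x2, y2)} box as \code{[x, y, x+w, y+h]}; category ids are
#' preserved. Zero-area boxes and annotations pointing at unregistered images
#' are rejected with an error naming the offending record.
#'
#' @param path path to a COCO JSON file
#' @return a list of class \code{"cocoGroundTruth"} with elements
#'   \code{instances} (see \code{\link{emptyInstances}}), \code{images}
#'   (data.frame: image_id, width, height, file_name) and \code{categories}
#'   (data.frame: id, name)
#' @export
loadGroundTruth <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed COCO file '", path, "': ",
                                           conditionMessage(e)))
  for (field in c("images", "annotations", "categories"))
    if (is.null(doc[[field]])) stop("malformed COCO file: missing '", field, "'")
  img <- doc$images
  images <- data.frame(image_id = as.character(img$id),
                       width = as.numeric(img$width),
                       height = as.numeric(img$height),
                       file_name = if (!is.null(img$file_name))
                         as.character(img$file_name) else NA_character_,
                       stringsAsFactors = FALSE)
  cat_df <- data.frame(id = as.integer(doc$categories$id),
                       name = as.character(doc$categories$name),
                       stringsAsFactors = FALSE)
  ann <- doc$annotations
  if (is.null(ann) || NROW(ann) == 0L) {
    inst <- emptyInstances()
  } else {
    bb <- if (is.matrix(ann$bbox)) ann$bbox else do.call(rbind, ann$bbox)
    if (is.null(bb) || ncol(bb) != 4)
      stop("malformed COCO file: annotation bbox must be [x, y, w, h]")
    bad <- which(bb[, 3] <= 0 | bb[, 4] <= 0)
    if (length(bad))
      stop("zero-area box in annotation record id ", ann$id[bad[1]])
    inst <- data.frame(instance_id = as.character(ann$id),
                       image_id = as.character(ann$image_id),
                       x1 = bb[, 1], y1 = bb[, 2],
                       x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4],
                       class_id = as.integer(ann$category_id),
                       stringsAsFactors = FALSE)
    orphan <- which(!inst$image_id %in% images$image_id)
    if (length(orphan))
      stop("annotation record id ", inst$instance_id[orphan[1]],
           " references unregistered image ", inst$image_id[orphan[1]])
    known_cats <- c(cat_df$id, UNKNOWN_CLASS)
    badcat <- which(!inst$class_id %in% known_cats)
    if (length(badcat))
      stop("annotation record id ", inst$instance_id[badcat[1]],
           " uses unregistered category ", inst$class_id[badcat[1]])
  }
  structure(list(instances = inst, images = images, categories = cat_df),
            class = "cocoGroundTruth")
}

#' Write ground truth to a COCO-dialect JSON file
#'
#' Inverse of \code{\link{loadGroundTruth}}: boxes go back to
#' \code{[x, y, w, h]} with \code{w = x2-x1}, \code{h = y2-y1}. If any
#' instance carries the unknown sentinel, a category record named
#' \code{"unknown"} with id -1 is emitted so the file remains valid COCO.
#'
#' @param gt a \code{"cocoGroundTruth"} list (instances, images, categories)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGroundTruth <- function(gt, path) {
  inst <- gt$instances
  cats <- gt$categories
  if (any(inst$class_id == UNKNOWN_CLASS) && !UNKNOWN_CLASS %in% cats$id)
    cats <- rbind(cats, data.frame(id = UNKNOWN_CLASS, name = "unknown",
                                   stringsAsFactors = FALSE))
  ann <- lapply(seq_len(nrow(inst)), function(i) {
    list(id = inst$instance_id[i], image_id = inst$image_id[i],
         category_id = inst$class_id[i],
         bbox = c(inst$x1[i], inst$y1[i],
                  inst$x2[i] - inst$x1[i], inst$y2[i] - inst$y1[i]),
         area = (inst$x2[i] - inst$x1[i]) * (inst$y2[i] - inst$y1[i]),
         iscrowd = 0L)
  })
  img <- lapply(seq_len(nrow(gt$images)), function(i) {
    rec <- list(id = gt$images$image_id[i], width = gt$images$width[i],
                height = gt$images$height[i])
    if (!is.na(gt$images$file_name[i])) rec$file_name <- gt$images$file_name[i]
    rec
  })
  cat_list <- lapply(seq_len(nrow(cats)), function(i)
    list(id = cats$id[i], name = cats$name[i]))
  jsonlite::write_json(list(images = img, annotations = ann,
                            categories = cat_list),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections from a COCO results-format JSON file
#'
#' Records are \code{\{image_id, category_id, bbox [x,y,w,h], score\}},
#' optionally extended with a \code{logits} vector over known classes for
#' downstream energy scoring. The reserved category id -1 (or the string
#' \code{"unknown"}) maps to the \code{\link{UNKNOWN_CLASS}} sentinel. The
#' result is sorted stably by (image_id, descending score).
#'
#' @param path path to a results JSON file
#' @return detection data.frame (see \code{\link{emptyDetections}})
#' @export
loadDetections <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0L) return(emptyDetections())
  lab <- vapply(recs, function(r) {
    if (identical(r$category_id, "unknown")) UNKNOWN_CLASS
    else as.integer(r$category_id)
  }, integer(1))
  bb <- t(vapply(recs, function(r) as.numeric(unlist(r$bbox)), numeric(4)))
  score <- vapply(recs, function(r) as.numeric(r$score), numeric(1))
  if (any(score < 0 | score > 1))
    stop("detection score outside [0,1] in record ",
         which(score < 0 | score > 1)[1])
  det <- data.frame(image_id = vapply(recs, function(r) as.character(r$image_id),
                                      character(1)),
                    x1 = bb[, 1], y1 = bb[, 2],
                    x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4],
                    label = lab, score = score, stringsAsFactors = FALSE)
  det$logits <- I(lapply(recs, function(r)
    if (is.null(r$logits)) NULL else as.numeric(unlist(r$logits))))
  orderDetections(det)
}

#' Write detections to a COCO results-format JSON file
#'
#' @param det detection data.frame
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeDetections <- function(det, path) {
  recs <- lapply(seq_len(nrow(det)), function(i) {
    r <- list(image_id = det$image_id[i],
              category_id = det$label[i],
              bbox = c(det$x1[i], det$y1[i],
                       det$x2[i] - det$x1[i], det$y2[i] - det$y1[i]),
              score = det$score[i])
    lg <- det$logits[[i]]
    if (!is.null(lg)) r$logits <- lg
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
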