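#' Load an annotated eye-image dataset from disk
#'
#' Auto-detects between the two deposit layouts in use for annotated eye
#' images:
#' \describe{
#'   \item{table layout}{an `index.csv` or `annotations.csv` at the root
#'     with a `filename` column plus, per record, either a `mask` column of
#'     mask-image paths, ellipse columns (`cx, cy, a, b`, optional `angle`
#'     in radians), or a `polygon` column of `"x1 y1;x2 y2;..."` vertex
#'     strings (0-based pixel coordinates). Optional `class`, `blink`,
#'     `eye_present` columns.}
#'   \item{paired layout}{`images/` and `masks/` directories with matching
#'     filenames, or flat `<name>.png` images with `<name>_mask.png`
#'     siblings.}
#' }
#' Any other layout fails loudly. Records whose annotation is missing are
#' excluded with a warning. Ellipse/polygon annotations are rasterized to
#' binary masks at image resolution by [load_labeled_frames()] using the
#' pixel-centre membership rule (0-based coordinates, x right, y down).
#'
#' @param root Dataset directory.
#' @return A `dataset_index`: data frame with columns `image`, `mask`,
#'   `annotation` (`"mask"`, `"ellipse"`, `"polygon"`), ellipse/polygon
#'   parameter columns, `class`, `blink`, `eye_present`; dataset root in
#'   `attr(, "root")`. Empty directory gives an empty index.
#' @export
load_deposit <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  tab_file <- c(file.path(root, "index.csv"),
                file.path(root, "annotations.csv"))
  tab_file <- tab_file[file.exists(tab_file)]
  idx <- if (length(tab_file) > 0) {
    load_table_layout(root, tab_file[1])
  } else {
    load_paired_layout(root)
  }
  idx$class <- normalize_class(idx$class)
  structure(idx, root = root, class = c("dataset_index", "data.frame"))
}

empty_index <- function() {
  data.frame(image = character(0), mask = character(0),
             annotation = character(0), cx = numeric(0), cy = numeric(0),
             a = numeric(0), b = numeric(0), angle = numeric(0),
             polygon = character(0), class = character(0),
             blink = logical(0), eye_present = logical(0))
}

normalize_class <- function(cls) {
  map <- c("dark-mouse" = "mouse", "bright-2P" = "2P-mouse",
           "2p-mouse" = "2P-mouse", "2P" = "2P-mouse")
  out <- as.character(cls)
  hit <- out %in% names(map)
  out[hit] <- map[out[hit]]
  out
}

load_table_layout <- function(root, path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"filename" %in% names(tab))
    stop("annotation table lacks a 'filename' column: ", path)
  n <- nrow(tab)
  idx <- empty_index()
  col <- function(nm, default) if (nm %in% names(tab)) tab[[nm]] else
    rep(default, n)
  has_ellipse <- all(c("cx", "cy", "a", "b") %in% names(tab))
  keep <- logical(n)
  for (i in seq_len(n)) {
    img <- file.path(root, tab$filename[i])
    if (!file.exists(img)) {
      warning("missing image, record excluded: ", tab$filename[i])
      next
    }
    mask <- col("mask", NA_character_)[i]
    ann <- NA_character_
    if (!is.na(mask) && nzchar(mask) && file.exists(file.path(root, mask))) {
      ann <- "mask"
    } else if (has_ellipse && is.finite(tab$a[i]) && is.finite(tab$b[i])) {
      ann <- "ellipse"
    } else if ("polygon" %in% names(tab) && !is.na(tab$polygon[i]) &&
               nzchar(tab$polygon[i])) {
      ann <- "polygon"
    } else {
      warning("missing annotation, record excluded: ", tab$filename[i])
      next
    }
    keep[i] <- TRUE
    idx[nrow(idx) + 1, ] <- list(
      img, if (identical(ann, "mask")) file.path(root, mask) else
        NA_character_,
      ann,
      if (has_ellipse) tab$cx[i] else NA_real_,
      if (has_ellipse) tab$cy[i] else NA_real_,
      if (has_ellipse) tab$a[i] else NA_real_,
      if (has_ellipse) tab$b[i] else NA_real_,
      if ("angle" %in% names(tab)) tab$angle[i] else 0,
      if ("polygon" %in% names(tab)) tab$polygon[i] else NA_character_,
      as.character(col("class", "mouse")[i]),
      as.logical(col("blink", FALSE)[i]),
      as.logical(col("eye_present", TRUE)[i]))
  }
  idx
}

load_paired_layout <- function(root) {
  img_pat <- "\\.(png|tif|tiff|jpg|jpeg)$"
  idx <- empty_index()
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  if (dir.exists(img_dir) && dir.exists(msk_dir)) {
    imgs <- list.files(img_dir, pattern = img_pat, ignore.case = TRUE)
    for (f in imgs) {
      m <- file.path(msk_dir, f)
      if (!file.exists(m)) {
        warning("missing mask, record excluded: ", f)
        next
      }
      idx[nrow(idx) + 1, ] <- list(file.path(img_dir, f), m, "mask",
                                   NA_real_, NA_real_, NA_real_, NA_real_,
                                   0, NA_character_, "mouse", FALSE, TRUE)
    }
    return(idx)
  }
  files <- list.files(root, pattern = img_pat, ignore.case = TRUE)
  imgs <- files[!grepl("_mask\\.", files)]
  if (length(files) > 0 && length(imgs) == 0)
    stop("unrecognized dataset layout under ", root)
  for (f in imgs) {
    stem <- tools::file_path_sans_ext(f)
    cand <- files[grepl(paste0("^", stem, "_mask\\."), files)]
    if (length(cand) == 0) {
      warning("missing mask, record excluded: ", f)
      next
    }
    idx[nrow(idx) + 1, ] <- list(file.path(root, f),
                                 file.path(root, cand[1]), "mask",
                                 NA_real_, NA_real_, NA_real_, NA_real_, 0,
                                 NA_character_, "mouse", FALSE, TRUE)
  }
  idx
}

# even-odd rule point-in-polygon test at pixel centres; 0-based coords
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses) && denom != 0) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i]
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

rasterize_annotation <- function(rec, h, w) {
  if (rec$annotation == "ellipse") {
    # same pixel-centre membership rule as the synthetic renderer
    if (h != w) {
      x <- matrix(rep(0:(w - 1), each = h), nrow = h)
      y <- matrix(rep(0:(h - 1), times = w), nrow = h)
      dx <- x - rec$cx; dy <- y - rec$cy
      u <- (dx * cos(rec$angle) + dy * sin(rec$angle)) / rec$a
      v <- (-dx * sin(rec$angle) + dy * cos(rec$angle)) / rec$b
      return((u^2 + v^2 <= 1) * 1)
    }
    ellipse_mask(h, c(rec$cx, rec$cy), c(rec$a, rec$b), rec$angle)
  } else if (rec$annotation == "polygon") {
    pts <- do.call(rbind, lapply(strsplit(rec$polygon, ";")[[1]],
                                 function(s) as.numeric(strsplit(trimws(s),
                                                                 " +")[[1]])))
    x <- rep(0:(w - 1), each = h)
    y <- rep(0:(h - 1), times = w)
    matrix(point_in_polygon(x, y, pts[, 1], pts[, 2]) * 1, nrow = h)
  } else {
    stop("record has no rasterizable annotation")
  }
}

#' Materialize a dataset index into labelled frames
#'
#' Reads each image, obtains its binary pupil mask (from the mask file or by
#' rasterizing the ellipse/polygon annotation at image resolution), and
#' returns `labeled_frame`s.
#'
#' @param index A `dataset_index` from [load_deposit()].
#' @param which Optional record subset (row indices).
#' @return List of `labeled_frame`s with `class_tag` attributes.
#' @export
load_labeled_frames <- function(index, which = seq_len(nrow(index))) {
  lapply(which, function(i) {
    rec <- index[i, ]
    img <- read_gray_image(rec$image)
    mask <- if (rec$annotation == "mask") {
      (read_gray_image(rec$mask) > 0.5) * 1
    } else {
      rasterize_annotation(rec, nrow(img), ncol(img))
    }
    if (rec$blink) mask[] <- 0 # blink frames carry no visible pupil
    f <- structure(list(image = img, mask = mask,
                        eye_present = rec$eye_present, blink = rec$blink),
                   class = "labeled_frame")
    attr(f, "class_tag") <- rec$class
    f
  })
}

#' Class-by-blink count table for a dataset index
#'
#' @param index A `dataset_index`.
#' @return A contingency table of counts by `class` x `blink` with `Total`
#'   margins; margins sum to the index size.
#' @export
summarize_counts <- function(index) {
  if (nrow(index) == 0)
    return(as.table(matrix(0L, 1, 3,
                           dimnames = list(class = "Total",
                                           blink = c("FALSE", "TRUE",
                                                     "Total")))))
  tab <- table(class = index$class,
               blink = factor(index$blink, levels = c(FALSE, TRUE)))
  stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
}
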