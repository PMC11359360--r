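#' Labelled point cloud
#'
#' Container for a 3D point cloud with an optional binary per-point class
#' label (0 = other, 1 = stem). Coordinates are stored as 64-bit doubles in
#' whatever units the source file used.
#'
#' @param points numeric matrix with M rows and 3 columns (x, y, z).
#' @param labels optional integer vector of length M with values in
#'   \{0, 1\}; 1 marks stem points.
#' @param origin_id string identifying the source specimen; augmentation
#'   variants of one specimen share the id.
#' @param variant one of `"original"`, `"rotated"`, `"jittered"`,
#'   `"noised"`.
#' @return an object of class `labeled_cloud`.
#' @export
labeled_cloud <- function(points, labels = NULL, origin_id = "",
                          variant = "original") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("points must have 3 columns, got %d", ncol(points))
  if (nrow(points) < 1L) stopf("a cloud needs at least one point")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stopf("points must be finite")
  colnames(points) <- c("x", "y", "z")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(points))
      stopf("labels length %d does not match %d points", length(labels), nrow(points))
    if (!all(labels %in% c(0L, 1L)))
      stopf("labels must be 0 (other) or 1 (stem)")
  }
  variant <- match.arg(variant, c("original", "rotated", "jittered", "noised"))
  structure(list(points = points, labels = labels,
                 origin_id = as.character(origin_id), variant = variant),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud> %d points, labels %s, origin '%s', variant '%s'\n",
              nrow(x$points),
              if (is.null(x$labels)) "absent"
              else sprintf("present (%d stem)", sum(x$labels == 1L)),
              x$origin_id, x$variant))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

#' Class names in label order
#' @return `c("other", "stem")`: label 0 is "other", label 1 is "stem".
#' @export
class_names <- function() c("other", "stem")

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = "ply", pcd = "pcd",
         xyz = "xyzl", xyzl = "xyzl", txt = "xyzl",
         stopf("cannot infer point-cloud format from extension '.%s'", ext))
}

#' Read a labelled point cloud
#'
#' Supports ASCII PLY (vertex properties x, y, z and optionally label),
#' PCD v0.7 ASCII (FIELDS x y z \[label\]) and plain whitespace-separated
#' XYZ text with an optional fourth label column.
#'
#' @param path file to read.
#' @param format `"ply"`, `"pcd"`, `"xyzl"` or `"auto"` (from extension).
#' @param origin_id,variant metadata attached to the returned cloud;
#'   `origin_id` defaults to the file stem.
#' @return a [labeled_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyzl"),
                       origin_id = NULL, variant = "original") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- guess_format(path)
  origin_id <- origin_id %||% tools::file_path_sans_ext(basename(path))
  parsed <- switch(format,
                   ply = read_ply(path),
                   pcd = read_pcd(path),
                   xyzl = read_xyzl(path))
  labeled_cloud(parsed$points, parsed$labels, origin_id = origin_id,
                variant = variant)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stopf("%s: not a PLY file (missing 'ply' magic)", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stopf("%s: PLY header has no end_header", path)
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stopf("%s: only ASCII PLY is supported", path)
  vline <- grep("^element vertex ", header, value = TRUE)
  if (!length(vline)) stopf("%s: PLY header lacks a vertex element", path)
  m <- as.integer(strsplit(vline[1], "\\s+")[[1]][3])
  # property names of the vertex element, in declaration order
  vstart <- match(vline[1], header)
  props <- character(0)
  for (h in header[seq(vstart + 1L, end)]) {
    if (grepl("^property ", h)) {
      props <- c(props, strsplit(h, "\\s+")[[1]][3])
    } else if (grepl("^element ", h) || h == "end_header") break
  }
  body <- lines[seq(end + 1L, length.out = m)]
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(props))) {
    bad <- which(nf != length(props))[1]
    stopf("%s: vertex record %d has %d fields, expected %d",
          path, bad, nf[bad], length(props))
  }
  vals <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                 nrow = m, byrow = TRUE)
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))[1]
    stopf("%s: vertex record %d is not numeric", path, bad)
  }
  colnames(vals) <- props
  need <- c("x", "y", "z")
  if (!all(need %in% props)) stopf("%s: PLY vertex needs x, y, z properties", path)
  labels <- if ("label" %in% props) as.integer(vals[, "label"]) else NULL
  list(points = vals[, need, drop = FALSE], labels = labels)
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dl <- grep("^DATA\\b", lines)
  if (!length(dl)) stopf("%s: PCD header has no DATA line", path)
  dl <- dl[1]
  if (!grepl("ascii", lines[dl])) stopf("%s: only ASCII PCD is supported", path)
  header <- lines[seq_len(dl)]
  fl <- grep("^FIELDS ", header, value = TRUE)
  if (!length(fl)) stopf("%s: PCD header has no FIELDS line", path)
  fields <- strsplit(trimws(fl[1]), "\\s+")[[1]][-1]
  pl <- grep("^POINTS ", header, value = TRUE)
  m <- as.integer(strsplit(pl[1], "\\s+")[[1]][2])
  body <- lines[seq(dl + 1L, length.out = m)]
  toks <- strsplit(trimws(body), "\\s+")
  nf <- lengths(toks)
  if (any(nf != length(fields))) {
    bad <- which(nf != length(fields))[1]
    stopf("%s: point record %d has %d fields, expected %d",
          path, bad, nf[bad], length(fields))
  }
  vals <- matrix(suppressWarnings(as.numeric(unlist(toks))),
                 nrow = m, byrow = TRUE)
  if (anyNA(vals)) stopf("%s: non-numeric point record", path)
  colnames(vals) <- fields
  labels <- if ("label" %in% fields) as.integer(vals[, "label"]) else NULL
  list(points = vals[, c("x", "y", "z"), drop = FALSE], labels = labels)
}

read_xyzl <- function(path) {
  tab <- tryCatch(read.table(path, header = FALSE),
                  error = function(e) stopf("%s: parse error: %s", path,
                                            conditionMessage(e)))
  if (ncol(tab) < 3L) stopf("%s: need at least 3 coordinate columns", path)
  points <- as.matrix(tab[, 1:3])
  labels <- if (ncol(tab) >= 4L) as.integer(tab[, 4]) else NULL
  list(points = points, labels = labels)
}

#' Write a labelled point cloud
#'
#' Round-trips exactly through [read_cloud()] (coordinates to full double
#' precision, labels exactly). With `colorize = TRUE` the PLY output also
#' carries per-vertex RGB: green (0, 255, 0) for stem points and blue
#' (0, 0, 255) for all other points, the colour convention used when
#' displaying segmentations.
#'
#' @param cloud a [labeled_cloud()].
#' @param path output file.
#' @param format `"ply"`, `"pcd"`, `"xyzl"` or `"auto"` (from extension).
#' @param colorize write RGB columns derived from the labels (PLY only).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyzl"),
                        colorize = FALSE) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (colorize && is.null(cloud$labels))
    stopf("colorize requires a labelled cloud")
  if (colorize && format != "ply")
    stopf("colorize is only supported for PLY output")
  switch(format,
         ply = write_ply(cloud, path, colorize),
         pcd = write_pcd(cloud, path),
         xyzl = write_xyzl(cloud, path))
  invisible(path)
}

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

write_ply <- function(cloud, path, colorize) {
  m <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", m),
              "property double x", "property double y", "property double z")
  if (has_lab) header <- c(header, "property int label")
  if (colorize) header <- c(header,
                            "property uchar red", "property uchar green",
                            "property uchar blue")
  header <- c(header, "end_header")
  cols <- apply(cloud$points, 2, fmt_num)
  if (m == 1L) cols <- matrix(cols, nrow = 1L)
  if (has_lab) cols <- cbind(cols, as.character(cloud$labels))
  if (colorize) {
    rgb <- ifelse(cloud$labels == 1L,
                  "0 255 0",   # stem: green
                  "0 0 255")   # other: blue
    cols <- cbind(cols, rgb)
  }
  writeLines(c(header, apply(cols, 1, paste, collapse = " ")), path)
}

write_pcd <- function(cloud, path) {
  m <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  fields <- if (has_lab) "x y z label" else "x y z"
  nf <- if (has_lab) 4L else 3L
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7",
              paste("FIELDS", fields),
              paste("SIZE", paste(rep(8, nf), collapse = " ")),
              paste("TYPE", paste(c("F", "F", "F", "I")[seq_len(nf)], collapse = " ")),
              paste("COUNT", paste(rep(1, nf), collapse = " ")),
              sprintf("WIDTH %d", m), "HEIGHT 1",
              "VIEWPOINT 0 0 0 1 0 0 0",
              sprintf("POINTS %d", m), "DATA ascii")
  cols <- apply(cloud$points, 2, fmt_num)
  if (m == 1L) cols <- matrix(cols, nrow = 1L)
  if (has_lab) cols <- cbind(cols, as.character(cloud$labels))
  writeLines(c(header, apply(cols, 1, paste, collapse = " ")), path)
}

write_xyzl <- function(cloud, path) {
  cols <- apply(cloud$points, 2, fmt_num)
  if (n_points(cloud) == 1L) cols <- matrix(cols, nrow = 1L)
  if (!is.null(cloud$labels)) cols <- cbind(cols, as.character(cloud$labels))
  writeLines(apply(cols, 1, paste, collapse = " "), path)
}

#' Dataset manifest
#'
#' A manifest is a data frame with one row per stored cloud and columns
#' `path`, `origin_id`, `variant` and `split` (empty until a split is
#' assigned). Every (origin_id, variant) pair must be unique so grouped
#' splitting is well defined.
#'
#' @param path,origin_id,variant,split character vectors of equal length.
#' @return a `dataset_manifest` data frame.
#' @export
dataset_manifest <- function(path = character(), origin_id = character(),
                             variant = character(),
                             split = rep("", length(path))) {
  stopifnot(length(origin_id) == length(path),
            length(variant) == length(path))
  if (any(!nzchar(origin_id))) stopf("origin_ids must be non-empty")
  key <- paste(origin_id, variant)
  if (anyDuplicated(key))
    stopf("duplicate (origin_id, variant) pair: %s", key[duplicated(key)][1])
  structure(data.frame(path = as.character(path),
                       origin_id = as.character(origin_id),
                       variant = as.character(variant),
                       split = as.character(split),
                       stringsAsFactors = FALSE),
            class = c("dataset_manifest", "data.frame"))
}

#' @rdname dataset_manifest
#' @param manifest a `dataset_manifest`.
#' @param file file for the tab-separated manifest table.
#' @export
write_manifest <- function(manifest, file) {
  write.table(as.data.frame(manifest), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname dataset_manifest
#' @export
read_manifest <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  dataset_manifest(tab$path, tab$origin_id, tab$variant,
                   tab$split %||% rep("", nrow(tab)))
}

resolve_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":")[[1]])
    if (length(parts) != 2L || anyNA(parts) || any(parts <= 0))
      stopf("ratio string must look like '4:1'")
    return(parts[1] / sum(parts))
  }
  ratio <- as.numeric(ratio)
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1)
    stopf("ratio must be in (0, 1) or a 'a:b' string")
  ratio
}

#' Grouped train/test split
#'
#' Splits at the level of original specimens so that augmentation variants of
#' one specimen never leak across the partition: origins are shuffled under
#' the seed, `floor(fraction * n_origins)` origins go to the training side
#' and every manifest entry follows its origin. A "4:1" ratio resolves to a
#' train fraction of 0.8; with 298 origins and 4 variants each this yields
#' the 952/240 entry split.
#'
#' @param manifest a [dataset_manifest()].
#' @param ratio train fraction in (0, 1), or an `"a:b"` string such as
#'   `"4:1"`.
#' @param seed integer seed controlling the origin shuffle.
#' @return a `split_result`: list with `train` and `test` manifest subsets
#'   and the resolved `ratio`.
#' @export
split_grouped <- function(manifest, ratio = "4:1", seed = 1L) {
  frac <- resolve_ratio(ratio)
  origins <- unique(manifest$origin_id)
  if (length(origins) < 2L) stopf("need at least 2 origins to split")
  shuffled <- with_seed(seed, sample(origins))
  n_train <- floor(frac * length(origins))
  train_origins <- shuffled[seq_len(n_train)]
  in_train <- manifest$origin_id %in% train_origins
  train <- manifest[in_train, , drop = FALSE]
  test <- manifest[!in_train, , drop = FALSE]
  train$split <- rep("train", nrow(train))
  test$split <- rep("test", nrow(test))
  structure(list(train = train, test = test, ratio = frac),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> train %d entries (%d origins), test %d entries (%d origins), fraction %.3f\n",
              nrow(x$train), length(unique(x$train$origin_id)),
              nrow(x$test), length(unique(x$test$origin_id)), x$ratio))
  invisible(x)
}

#' Grouped k-fold partition
#'
#' Origins are shuffled under the seed and dealt into `k` folds whose sizes
#' differ by at most one origin; each fold in turn is the validation side.
#'
#' @inheritParams split_grouped
#' @param k number of folds (>= 2).
#' @return list of `k` `split_result` objects; `test` holds the validation
#'   fold.
#' @export
kfold_grouped <- function(manifest, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stopf("k must be at least 2")
  origins <- unique(manifest$origin_id)
  if (k > length(origins)) stopf("k = %d exceeds %d origins", k, length(origins))
  shuffled <- with_seed(seed, sample(origins))
  fold_id <- rep(seq_len(k), length.out = 0)
  sizes <- rep(length(origins) %/% k, k)
  extra <- length(origins) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_id <- rep(seq_len(k), times = sizes)
  lapply(seq_len(k), function(f) {
    val_origins <- shuffled[fold_id == f]
    in_val <- manifest$origin_id %in% val_origins
    train <- manifest[!in_val, , drop = FALSE]
    test <- manifest[in_val, , drop = FALSE]
    train$split <- rep("train", nrow(train))
    test$split <- rep("val", nrow(test))
    structure(list(train = train, test = test, ratio = (k - 1) / k),
              class = "split_result")
  })
}
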