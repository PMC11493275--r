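## File I/O: XYZ text, minimal LAS 1.2, ESRI ASCII grid, tree tables,
## DCF-style configuration files.

#' Write a point cloud as XYZ text
#'
#' Space-separated `x y z class` with one header line.
#'
#' @param cloud a [point_cloud].
#' @param path output file path.
#' @export
write_xyz <- function(cloud, path) {
  df <- data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                   z = cloud$points[, 3], class = cloud$class)
  utils::write.table(df, path, sep = " ", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a point cloud from XYZ text
#'
#' Accepts the output of [write_xyz()] or bare `x y z` columns.
#'
#' @param path input file path.
#' @param source cloud provenance label.
#' @export
read_xyz <- function(path, source = "synthetic") {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  cls <- if ("class" %in% names(df)) df$class else rep("unclassified", nrow(df))
  point_cloud(cbind(df$x, df$y, df$z), cls, source = source)
}

## LAS 1.2 classification codes <-> package labels
.las_class_to_label <- function(code) {
  out <- rep("unclassified", length(code))
  out[code == 2L] <- "ground"
  out[code == 5L] <- "high_vegetation"
  out
}
.label_to_las_class <- function(label) {
  out <- rep(1L, length(label))
  out[label == "ground"] <- 2L
  out[label == "high_vegetation"] <- 5L
  out
}

#' Write a point cloud as LAS 1.2 (point data format 0)
#'
#' Minimal writer covering coordinates and ASPRS classification
#' (1 = unclassified, 2 = ground, 5 = high vegetation).
#'
#' @param cloud a [point_cloud].
#' @param path output `.las` path.
#' @param scale coordinate scale factor stored in the header.
#' @export
write_las <- function(cloud, path, scale = 0.001) {
  n <- nrow(cloud$points)
  off <- if (n) apply(cloud$points, 2, min) else c(0, 0, 0)
  con <- file(path, "wb"); on.exit(close(con))
  wU16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wU32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wDbl <- function(x) writeBin(as.double(x), con, size = 8, endian = "little")
  writeChar("LASF", con, 4, eos = NULL)
  wU16(0); wU16(0); wU32(0)                         # source id, encoding, GUID1
  wU16(0); wU16(0)                                  # GUID2, GUID3
  writeBin(raw(8), con)                             # GUID4
  writeBin(as.raw(c(1L, 2L)), con)                  # version 1.2
  writeChar(formatC("canopyAGB", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("canopyAGB R package", width = 32, flag = "-"), con, 32, eos = NULL)
  wU16(1); wU16(2024)                               # day of year, year
  wU16(227)                                         # header size
  wU32(227)                                         # offset to point data
  wU32(0)                                           # number of VLRs
  writeBin(as.raw(0L), con)                         # point data format 0
  wU16(20)                                          # point record length
  wU32(n)                                           # number of point records
  wU32(c(n, 0L, 0L, 0L, 0L))                        # points by return
  wDbl(rep(scale, 3))                               # x/y/z scale
  wDbl(off)                                         # x/y/z offset
  rng <- if (n) apply(cloud$points, 2, range) else matrix(0, 2, 3)
  wDbl(c(rng[2, 1], rng[1, 1], rng[2, 2], rng[1, 2], rng[2, 3], rng[1, 3]))
  if (n) {
    xyz <- sweep(cloud$points, 2, off)
    xyz <- round(sweep(xyz, 2, rep(scale, 3), "/"))
    cls <- .label_to_las_class(cloud$class)
    rec <- raw(20L * n)
    ints <- matrix(as.integer(xyz), ncol = 3)
    for (i in seq_len(n)) {
      o <- 20L * (i - 1L)
      rec[o + 1:12] <- writeBin(ints[i, ], raw(), size = 4, endian = "little")
      rec[o + 13:14] <- writeBin(0L, raw(), size = 2, endian = "little")
      rec[o + 15] <- as.raw(bitwOr(1L, bitwShiftL(1L, 3L)))  # return 1 of 1
      rec[o + 16] <- as.raw(cls[i])
      rec[o + 17] <- as.raw(0L)                              # scan angle
      rec[o + 18] <- as.raw(0L)                              # user data
      rec[o + 19:20] <- writeBin(0L, raw(), size = 2, endian = "little")
    }
    writeBin(rec, con)
  }
  invisible(path)
}

#' Read a LAS 1.x file (point data formats 0-3)
#'
#' Reads coordinates and classification; other attributes are ignored.
#'
#' @param path input `.las` path.
#' @param source cloud provenance label.
#' @export
read_las <- function(path, source = "ALS") {
  con <- file(path, "rb"); on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop_("%s is not a LAS file", path)
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 1, 4, endian = "little")            # n VLRs
  fmt <- as.integer(readBin(con, "raw", 1))
  reclen <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  n <- readBin(con, "integer", 1, 4, endian = "little")
  seek(con, 131)
  scale <- readBin(con, "double", 3, 8, endian = "little")
  off <- readBin(con, "double", 3, 8, endian = "little")
  seek(con, offset_to_points)
  rec <- readBin(con, "raw", reclen * n)
  dim(rec) <- c(reclen, n)
  ints <- vapply(1:3, function(k)
    readBin(as.vector(rec[(4 * k - 3):(4 * k), ]), "integer", n, 4,
            endian = "little"), integer(n))
  if (n == 1L) ints <- matrix(ints, nrow = 1)
  xyz <- sweep(sweep(ints, 2, scale, "*"), 2, off, "+")
  cls <- as.integer(rec[16, ])
  point_cloud(xyz, .las_class_to_label(cls), source = source)
}

#' Write a raster grid as ESRI ASCII grid text
#'
#' @param grid a [raster_grid].
#' @param path output `.asc` path.
#' @param nodata value written for NA cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  yll <- grid$origin[2] - grid$n_rows * grid$cell_size
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  v <- grid$values
  v[!is.finite(v)] <- nodata
  lines <- apply(v, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input `.asc` path.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  raster_grid(origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
              cell_size = hdr$cellsize, values = vals)
}

#' Write / read a tree attribute table
#'
#' CSV with header `tree_id,plot_id,species,x,y,H_m,DBH_cm,R_m` plus any
#' extra columns present (e.g. `W_ref_kg`, `source`).
#'
#' @param trees a `tree_records` data frame.
#' @param path file path.
#' @export
write_tree_csv <- function(trees, path) {
  utils::write.csv(trees, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tree_csv
#' @export
read_tree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tree_records(df)
}

#' Read a per-tree table with arbitrary column names
#'
#' Reads CSV or XLSX (XLSX requires the `readxl` package) and renames
#' columns via `mapping`, a named character vector of
#' `standard_name = file_column`.  Standard names: `plot_id`, `species`,
#' `H_m`, `DBH_cm`, `R_m`, and optionally `tree_id`, `x`, `y`.
#'
#' @param path CSV or XLSX file.
#' @param mapping named character vector mapping standard to file columns.
#' @export
read_tree_table <- function(path, mapping = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_("reading XLSX requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(mapping)) {
    miss <- setdiff(unname(mapping), names(df))
    if (length(miss)) stop_("mapped column(s) not in file: %s",
                            paste(miss, collapse = ", "))
    for (std in names(mapping)) names(df)[names(df) == mapping[[std]]] <- std
  }
  need <- c("plot_id", "species", "H_m", "DBH_cm", "R_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("tree table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"tree_id" %in% names(df)) df$tree_id <- seq_len(nrow(df))
  if (!"x" %in% names(df)) df$x <- NA_real_
  if (!"y" %in% names(df)) df$y <- NA_real_
  as_tree_records(df)
}

#' Read a forest configuration file
#'
#' Debian-control-style text: blank-line-separated blocks of `Key: value`
#' pairs.  The first block holds global keys (`min_spacing`, `seed`); each
#' following block describes one plot (`plot_id`, `species`, `count`,
#' `extent` as `"w x h"`, `crown_shape`, and the attribute ranges
#' `H_range`, `DBH_range`, `R_range` as `"min max"`).
#'
#' @param path configuration file path.
#' @return A [forest_config].
#' @export
read_forest_config <- function(path) {
  dcf <- read.dcf(path)
  blocks <- lapply(seq_len(nrow(dcf)), function(i) {
    r <- dcf[i, ]; as.list(r[!is.na(r)])
  })
  glob <- blocks[[1]]
  num2 <- function(s) as.numeric(strsplit(trimws(s), "[ x,]+")[[1]])
  plots <- lapply(blocks[-1], function(b) {
    prof <- species_profile(
      species_id = b$species,
      H_range = num2(b$H_range), DBH_range = num2(b$DBH_range),
      R_range = num2(b$R_range),
      crown_shape = b$crown_shape %||% NULL)
    plot_spec(plot_id = as.integer(b$plot_id), profile = prof,
              extent = num2(b$extent), count = as.integer(b$count))
  })
  forest_config(plots = plots,
                min_spacing = as.numeric(glob$min_spacing %||% 2),
                seed = as.integer(glob$seed %||% 1))
}
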