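#' Read a point cloud from disk
#'
#' Reads PLY (ASCII or binary little-endian) or CSV files into a
#' [point_cloud]. Point order and coordinate values are preserved exactly;
#' colours are populated iff present in the file. Vertex properties other
#' than `x`/`y`/`z`/`red`/`green`/`blue` are ignored with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (from the extension), `"ply"` or `"csv"`. CSV files
#'   need columns `x,y,z` and optionally `r,g,b`.
#' @return a [point_cloud]; `source_id` is set to the file name.
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "ply", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", csv = "csv", xyz = "csv",
                     stop("cannot infer point-cloud format from extension '",
                          ext, "'; pass format = 'ply' or 'csv'"))
  }
  if (format == "ply") read_ply(path) else read_csv_cloud(path)
}

#' Write a point cloud to disk
#'
#' The written file reads back into an equal cloud: exactly for binary PLY
#' (coordinates are stored as 64-bit floats) and CSV, and to better than
#' 1e-6 m for ASCII PLY.
#'
#' @param cloud a [point_cloud].
#' @param path output file path.
#' @param format `"ply"` or `"csv"`.
#' @param binary write binary little-endian PLY (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("ply", "csv"), binary = TRUE) {
  stopifnot(is_point_cloud(cloud))
  format <- match.arg(format)
  if (format == "ply") write_ply(cloud, path, binary = binary)
  else write_csv_cloud(cloud, path)
  invisible(path)
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(size = 1L, what = "integer", signed = TRUE),
    uchar = , uint8 = list(size = 1L, what = "integer", signed = FALSE),
    short = , int16 = list(size = 2L, what = "integer", signed = TRUE),
    ushort = , uint16 = list(size = 2L, what = "integer", signed = FALSE),
    int = , int32 = list(size = 4L, what = "integer", signed = TRUE),
    uint = , uint32 = list(size = 4L, what = "integer", signed = TRUE),
    float = , float32 = list(size = 4L, what = "double", signed = TRUE),
    double = , float64 = list(size = 8L, what = "double", signed = TRUE),
    stop("unsupported PLY property type '", type, "'"))
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  end_pos <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(end_pos) == 0L) stop("malformed PLY '", path, "': no end_header")
  nl <- which(raw[end_pos[1L]:length(raw)] == as.raw(10L))[1L]
  if (is.na(nl)) stop("malformed PLY '", path, "': no newline after end_header")
  header_len <- end_pos[1L] + nl - 1L
  header <- strsplit(rawToChar(raw[seq_len(header_len)]), "\r?\n")[[1L]]
  if (length(header) == 0L || trimws(header[1L]) != "ply")
    stop("malformed PLY '", path, "': missing 'ply' magic line")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop("malformed PLY '", path, "': bad format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' (big-endian is not supported)")

  # parse the element declarations; the vertex element must come first
  props <- character(0); types <- character(0); n_vertex <- NA_integer_
  in_vertex <- FALSE; seen_first_element <- FALSE
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "element") {
      if (!seen_first_element) {
        if (tok[2L] != "vertex")
          stop("unsupported PLY '", path, "': first element is '", tok[2L],
               "', expected 'vertex'")
        n_vertex <- as.integer(tok[3L]); in_vertex <- TRUE
        seen_first_element <- TRUE
      } else in_vertex <- FALSE
    } else if (tok[1L] == "property" && in_vertex) {
      if (tok[2L] == "list")
        stop("unsupported PLY '", path, "': list property in vertex element")
      types <- c(types, tok[2L]); props <- c(props, tok[3L])
    }
  }
  if (is.na(n_vertex)) stop("malformed PLY '", path, "': no vertex element")

  known <- c("x", "y", "z", "red", "green", "blue")
  if (!all(c("x", "y", "z") %in% props))
    stop("malformed PLY '", path, "': vertex element lacks x/y/z properties")
  if (any(!props %in% known))
    warning("ignoring PLY vertex properties: ",
            paste(setdiff(props, known), collapse = ", "))

  if (n_vertex == 0L) {
    cols <- list()
  } else if (fmt == "ascii") {
    body <- rawToChar(raw[(header_len + 1L):length(raw)])
    vals <- scan(text = body, what = double(), n = n_vertex * length(props),
                 quiet = TRUE)
    if (length(vals) < n_vertex * length(props))
      stop("malformed PLY '", path, "': expected ", n_vertex,
           " vertices but data ends at vertex ",
           length(vals) %/% length(props) + 1L)
    m <- matrix(vals, ncol = length(props), byrow = TRUE)
    cols <- lapply(seq_along(props), function(j) m[, j])
  } else {
    info <- lapply(types, ply_type_info)
    sizes <- vapply(info, `[[`, integer(1L), "size")
    row_size <- sum(sizes)
    need <- header_len + n_vertex * row_size
    if (length(raw) < need)
      stop("malformed PLY '", path, "': binary payload truncated at vertex ",
           (length(raw) - header_len) %/% row_size + 1L)
    offsets <- c(0L, cumsum(sizes))[seq_along(props)]
    cols <- lapply(seq_along(props), function(j) {
      sz <- sizes[j]
      start <- header_len + offsets[j] +
        rep(seq(0L, by = row_size, length.out = n_vertex), each = sz) +
        rep(seq_len(sz), times = n_vertex)
      readBin(raw[start], info[[j]]$what, n = n_vertex, size = sz,
              signed = info[[j]]$signed, endian = "little")
    })
  }
  names(cols) <- props[seq_along(cols)]
  grab <- function(p) if (n_vertex == 0L) numeric(0) else cols[[p]]
  pts <- cbind(x = grab("x"), y = grab("y"), z = grab("z"))
  if (n_vertex == 0L) pts <- matrix(numeric(0), 0L, 3L,
                                    dimnames = list(NULL, c("x", "y", "z")))
  colors <- NULL
  if (all(c("red", "green", "blue") %in% props)) {
    colors <- cbind(r = as.integer(grab("red")), g = as.integer(grab("green")),
                    b = as.integer(grab("blue")))
    if (n_vertex == 0L) colors <- matrix(integer(0), 0L, 3L)
  }
  point_cloud(pts, colors, source_id = basename(path))
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- n_points(cloud)
  has_col <- !is.null(cloud$colors)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment written by pigweigh",
    paste("element vertex", n),
    "property double x", "property double y", "property double z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  if (n == 0L) return(invisible(path))
  if (binary) {
    pts_raw <- writeBin(as.vector(t(cloud$points)), raw(), size = 8L,
                        endian = "little")
    if (has_col) {
      pm <- matrix(pts_raw, nrow = 24L)
      cm <- matrix(as.raw(t(cloud$colors)), nrow = 3L)
      writeBin(as.vector(rbind(pm, cm)), con)
    } else writeBin(pts_raw, con)
  } else {
    coord <- sprintf("%.10g %.10g %.10g",
                     cloud$points[, 1L], cloud$points[, 2L], cloud$points[, 3L])
    if (has_col)
      coord <- paste(coord, cloud$colors[, 1L], cloud$colors[, 2L],
                     cloud$colors[, 3L])
    writeBin(charToRaw(paste0(paste(coord, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

read_csv_cloud <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("malformed cloud CSV '", path, "': needs columns x, y, z")
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad) || anyNA(v))
      stop("malformed cloud CSV '", path, "': non-numeric '", cc,
           "' at row ", c(bad, which(is.na(v)))[1L])
    df[[cc]] <- v
  }
  colors <- NULL
  cn <- if (all(c("r", "g", "b") %in% names(df))) c("r", "g", "b")
        else if (all(c("red", "green", "blue") %in% names(df)))
          c("red", "green", "blue")
  if (!is.null(cn)) colors <- cbind(df[[cn[1]]], df[[cn[2]]], df[[cn[3]]])
  point_cloud(cbind(df$x, df$y, df$z), colors, source_id = basename(path))
}

write_csv_cloud <- function(cloud, path) {
  df <- as.data.frame(cloud$points)
  if (!is.null(cloud$colors)) df <- cbind(df, as.data.frame(cloud$colors))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scale-weight table
#'
#' Reads a CSV keyed by animal ID with one scale weight per row. The header
#' must contain `animal_id` and a weight column (`weight_kg` or `weight`);
#' an optional date column (`capture_date` or `date`) is carried through.
#'
#' @param path CSV file path.
#' @return data.frame with columns `animal_id` (character), `weight_kg`
#'   (numeric, kg) and `capture_date` (character, possibly empty).
#' @details Weights must be strictly positive and below 300 kg (a sanity
#'   bound well above the 20--120 kg range of grow-finish pigs); violations
#'   raise an error citing the row number.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  wcol <- intersect(c("weight_kg", "weight"), names(df))[1L]
  if (!"animal_id" %in% names(df) || is.na(wcol))
    stop("weight table '", path,
         "' needs columns 'animal_id' and 'weight_kg' (or 'weight')")
  w <- suppressWarnings(as.numeric(df[[wcol]]))
  bad <- which(is.na(w) | w <= 0 | w >= 300)
  if (length(bad))
    stop("invalid weight at row ", bad[1L], " of '", path, "': '",
         df[[wcol]][bad[1L]], "' (must be a number in (0, 300) kg)")
  dcol <- intersect(c("capture_date", "date"), names(df))[1L]
  data.frame(animal_id = as.character(df$animal_id), weight_kg = w,
             capture_date = if (!is.na(dcol)) as.character(df[[dcol]]) else "",
             stringsAsFactors = FALSE)
}
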