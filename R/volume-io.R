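#' Read and write 3D volumes (NIfTI or NRRD)
#'
#' `readVolume` dispatches on the file extension: `.nii` / `.nii.gz` are
#' handled through the RNifti library; `.nrrd` files are parsed directly
#' (raw or gzip encodings, 3D, axis-aligned `space directions`).
#' `writeVolume` writes the same formats. Round-tripping preserves the
#' intensity grid exactly and spacing/origin to float precision.
#'
#' Only axis-aligned geometries (no rotation in the affine / space
#' directions) are supported; anything else raises a format error rather
#' than silently dropping orientation.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param v a [CTVolume-class].
#' @return `readVolume`: a [CTVolume-class]. `writeVolume`: the path,
#'   invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) readNiftiVolume(path)
  else if (grepl("\\.nrrd$", path)) readNrrdVolume(path)
  else stop("unsupported volume format (expected .nii, .nii.gz or .nrrd): ",
            path)
}

#' @rdname readVolume
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "CTVolume"))
  if (grepl("\\.nii(\\.gz)?$", path)) writeNiftiVolume(v, path)
  else if (grepl("\\.nrrd$", path)) writeNrrdVolume(v, path)
  else stop("unsupported volume format (expected .nii, .nii.gz or .nrrd): ",
            path)
  invisible(path)
}

readNiftiVolume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (RNifti::ndim(img) != 3L) stop("expected a 3D NIfTI volume: ", path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-4 * max(abs(diag(rot)))))
    stop("NIfTI volume has a rotated affine; only axis-aligned volumes are supported: ",
         path)
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  ctVolume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
           origin = aff[1:3, 4])
}

writeNiftiVolume <- function(v, path) {
  aff <- diag(c(v@spacing, 1))
  aff[1:3, 4] <- v@origin
  img <- RNifti::asNifti(v@data,
    reference = list(pixdim = c(0, v@spacing, 1, 1, 1, 1)),
    datatype = "double")
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
}

# Minimal NRRD support: 3D, raw or gzip encoding, little-endian doubles on
# write; on read, any of the common scalar types.
readNrrdVolume <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  lf <- as.raw(10L)
  # header ends at the first blank line (LF LF, tolerating CR)
  hdr_end <- NA_integer_
  i <- 1L
  while (i < length(bytes)) {
    if (bytes[i] == lf &&
        (bytes[i + 1L] == lf ||
         (bytes[i + 1L] == as.raw(13L) && i + 2L <= length(bytes) &&
          bytes[i + 2L] == lf))) {
      hdr_end <- i
      break
    }
    i <- i + 1L
  }
  if (is.na(hdr_end)) stop("truncated NRRD header: ", path)
  data_start <- hdr_end + if (bytes[hdr_end + 1L] == lf) 2L else 3L
  lines <- strsplit(gsub("\r", "", rawToChar(bytes[1:(hdr_end - 1L)])),
                    "\n", fixed = TRUE)[[1]]
  if (!length(lines) || !grepl("^NRRD000", lines[1]))
    stop("not an NRRD file (bad magic): ", path)
  fields <- list()
  for (line in lines[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("NRRD header missing field '", k, "': ", path)
    fields[[k]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("expected a 3D NRRD volume: ", path)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  rtype <- switch(type,
    "double" = list(what = "double", size = 8L),
    "float" = list(what = "double", size = 4L),
    "short" = , "int16" = list(what = "integer", size = 2L),
    "int" = , "int32" = list(what = "integer", size = 4L),
    "uchar" = , "uint8" = list(what = "integer", size = 1L),
    stop("unsupported NRRD type '", type, "': ", path))
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  spacing <- rep(1, 3)
  origin <- rep(0, 3)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L) stop("unsupported NRRD space directions: ", path)
    M <- sapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
    if (any(abs(M[row(M) != col(M)]) > 1e-9))
      stop("NRRD volume has non-axis-aligned space directions: ", path)
    spacing <- diag(M)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  enc <- tolower(need("encoding"))
  payload <- if (data_start <= length(bytes))
    bytes[data_start:length(bytes)] else raw(0)
  if (enc %in% c("gzip", "gz"))
    payload <- tryCatch(memDecompress(payload, type = "gzip"),
                        error = function(e)
                          stop("corrupt gzip NRRD payload: ", path))
  else if (enc != "raw")
    stop("unsupported NRRD encoding '", enc, "': ", path)
  if (length(payload) < n * rtype$size)
    stop("truncated NRRD data (expected ", n * rtype$size, " bytes, got ",
         length(payload), "): ", path)
  vals <- readBin(payload, rtype$what, n = n, size = rtype$size,
                  endian = endian)
  if (length(vals) != n)
    stop("truncated NRRD data (expected ", n, " values, got ",
         length(vals), "): ", path)
  ctVolume(array(as.numeric(vals), dim = sizes), spacing = spacing,
           origin = origin)
}

writeNrrdVolume <- function(v, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c("NRRD0004",
    "# generated by CIlocate",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(v@data), collapse = " ")),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            v@spacing[1], v@spacing[2], v@spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            v@origin[1], v@origin[2], v@origin[3]),
    "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(v@data), con, size = 8L, endian = "little")
}

#' Read and write electrode coordinate lists
#'
#' CSV files use the header `electrode,x_mm,y_mm,z_mm` with electrodes
#' numbered 1..L from the base; JSON files carry the same records plus
#' optional metadata (`spec`, `insertion_angle_deg`).
#'
#' @param path a `.csv` or `.json` file.
#' @param coordsMat n x 3 matrix of mm positions, ordered base to apex.
#' @param electrode integer labels (default `1:n`).
#' @param meta named list of extra metadata for JSON output.
#' @return `readCoordinates`: a data.frame with columns `electrode`, `x_mm`,
#'   `y_mm`, `z_mm` (JSON metadata attached as attributes).
#' @export
readCoordinates <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$coordinates)
    for (k in setdiff(names(obj), "coordinates")) attr(df, k) <- obj[[k]]
  } else {
    df <- read.csv(path)
  }
  req <- c("electrode", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(df)))
    stop("coordinate file must have columns ", paste(req, collapse = ", "),
         ": ", path)
  df[order(df$electrode), req, drop = FALSE]
}

#' @rdname readCoordinates
#' @export
writeCoordinates <- function(coordsMat, path, electrode = seq_len(nrow(coordsMat)),
                             meta = list()) {
  df <- data.frame(electrode = electrode, x_mm = coordsMat[, 1],
                   y_mm = coordsMat[, 2], z_mm = coordsMat[, 3])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(c(meta, list(coordinates = df)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

coordsMatrix <- function(df) {
  as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
}

#' Extract a region of interest around the electrode array
#'
#' Crops an axis-aligned sub-volume whose faces keep at least `margin_mm`
#' distance from every ground-truth electrode position, mirroring the
#' manual ROI definition used around the array (3 mm, i.e. 10 voxels at
#' 0.3 mm spacing). The margin is applied per face; the crop is clipped at
#' the volume bounds with a warning. World coordinates of retained voxels
#' are unchanged (the origin is updated accordingly).
#'
#' @param v a [CTVolume-class].
#' @param gt n x 3 matrix of ground-truth positions (mm), or a data.frame
#'   from [readCoordinates()].
#' @param margin_mm minimum face distance to any GT point (default 3).
#' @return A [CTVolume-class] sub-volume.
#' @export
extractROI <- function(v, gt, margin_mm = 3.0) {
  if (is.data.frame(gt)) gt <- coordsMatrix(gt)
  gt <- rbindable(gt)
  if (nrow(gt) == 0L) stop("ground-truth coordinate list is empty")
  d <- dim(v@data)
  lo_w <- apply(gt, 2L, min) - margin_mm
  hi_w <- apply(gt, 2L, max) + margin_mm
  lo_i <- floor((lo_w - v@origin) / v@spacing) + 1
  hi_i <- ceiling((hi_w - v@origin) / v@spacing) + 1
  clip <- any(lo_i < 1) || any(hi_i > d)
  lo_i <- pmax(as.integer(lo_i), 1L)
  hi_i <- pmin(as.integer(hi_i), d)
  if (any(hi_i < lo_i)) stop("ROI does not intersect the volume")
  if (clip) warning("ROI clipped at volume bounds; margin not fully honored")
  sub <- v@data[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3],
                drop = FALSE]
  new("CTVolume", data = sub, spacing = v@spacing,
      origin = v@origin + (lo_i - 1) * v@spacing)
}
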