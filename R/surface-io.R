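# GIFTI and plain-array surface I/O.
#
# GIFTI files are XML with base64/gzip-encoded little-endian arrays; the
# reader supports ASCII, Base64Binary and GZipBase64Binary encodings and the
# FLOAT32/FLOAT64/INT32 data types, which covers surface geometry and
# per-vertex functional data. Triangle indices are 0-based on disk and
# converted to this package's 1-based convention.

gifti_type_info <- function(datatype) {
  switch(datatype,
    NIFTI_TYPE_FLOAT32 = list(what = "numeric", size = 4L),
    NIFTI_TYPE_FLOAT64 = list(what = "numeric", size = 8L),
    NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
    stop("unsupported GIFTI DataType: ", datatype))
}

decode_gifti_data <- function(data_node, datatype, encoding, endian, n) {
  txt <- xml2::xml_text(data_node)
  info <- gifti_type_info(datatype)
  rb_endian <- if (identical(endian, "BigEndian")) "big" else "little"
  if (encoding == "ASCII") {
    vals <- scan(text = txt, what = double(), quiet = TRUE)
    return(vals)
  }
  raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
  if (encoding == "GZipBase64Binary")
    raw <- memDecompress(raw, type = "gzip")
  else if (encoding != "Base64Binary")
    stop("unsupported GIFTI Encoding: ", encoding)
  readBin(raw, what = info$what, n = n, size = info$size, endian = rb_endian)
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(arrays, function(a) {
    att <- function(x, default = NULL) {
      v <- xml2::xml_attr(a, x)
      if (is.na(v)) default else v
    }
    ndim <- as.integer(att("Dimensionality", "1"))
    dims <- vapply(seq_len(ndim) - 1L,
                   function(i) as.integer(att(paste0("Dim", i), "1")),
                   integer(1))
    vals <- decode_gifti_data(xml2::xml_find_first(a, ".//Data"),
                              att("DataType"), att("Encoding", "ASCII"),
                              att("Endian", "LittleEndian"), prod(dims))
    if (length(vals) != prod(dims))
      stop("GIFTI data length mismatch in ", path)
    mat <- if (ndim >= 2 && dims[2] > 1) {
      order <- att("ArrayIndexingOrder", "RowMajorOrder")
      if (order == "RowMajorOrder")
        matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
      else matrix(vals, nrow = dims[1], ncol = dims[2])
    } else vals
    list(intent = att("Intent", "NIFTI_INTENT_NONE"), data = mat)
  })
}

encode_gifti_data <- function(values, datatype) {
  info <- gifti_type_info(datatype)
  if (info$what == "integer") values <- as.integer(values)
  raw <- writeBin(values, raw(), size = info$size, endian = "little")
  jsonlite::base64_enc(memCompress(raw, type = "gzip"))
}

gifti_data_array <- function(values, intent, datatype) {
  if (is.matrix(values)) {
    dims <- dim(values)
    flat <- as.vector(t(values))  # row-major on disk
    dim_attrs <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"',
                         dims[1], dims[2])
  } else {
    flat <- as.vector(values)
    dim_attrs <- sprintf('Dimensionality="1" Dim0="%d"', length(values))
  }
  paste0(
    '<DataArray Intent="', intent, '" DataType="', datatype,
    '" ArrayIndexingOrder="RowMajorOrder" ', dim_attrs,
    ' Encoding="GZipBase64Binary" Endian="LittleEndian"',
    ' ExternalFileName="" ExternalFileOffset="">\n<Data>',
    encode_gifti_data(flat, datatype),
    "</Data>\n</DataArray>")
}

write_gifti <- function(arrays_xml, path) {
  txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="', length(arrays_xml), '">\n',
    paste(arrays_xml, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(txt, path)
  invisible(path)
}

#' Write a surface mesh as a GIFTI file
#'
#' Emits one POINTSET (float32, mm) and one TRIANGLE (int32, 0-based)
#' data array, gzip+base64 encoded, little-endian.
#'
#' @param mesh a [surface_mesh()].
#' @param path output `.surf.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  write_gifti(c(
    gifti_data_array(mesh$vertices, "NIFTI_INTENT_POINTSET",
                     "NIFTI_TYPE_FLOAT32"),
    gifti_data_array(mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                     "NIFTI_TYPE_INT32")), path)
}

#' Read a surface mesh from a GIFTI file
#'
#' @param path `.surf.gii` path with POINTSET and TRIANGLE arrays.
#' @return A [surface_mesh()].
#' @export
read_gifti_surface <- function(path) {
  arrays <- read_gifti_arrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  pts <- arrays[[match("NIFTI_INTENT_POINTSET", intents)]]$data
  tri <- arrays[[match("NIFTI_INTENT_TRIANGLE", intents)]]$data
  if (is.null(pts) || is.null(tri))
    stop("GIFTI surface must contain POINTSET and TRIANGLE arrays")
  surface_mesh(pts, tri + 1L)
}

#' Write per-vertex metric data as a GIFTI functional file
#'
#' @param values numeric vector (one map) or matrix with one map per row
#'   (subjects x vertices); each map becomes one data array.
#' @param path output `.func.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_metric <- function(values, path) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  write_gifti(apply(values, 1, function(v)
    gifti_data_array(v, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32")), path)
}

#' Read per-vertex metric data from a GIFTI functional file
#'
#' @param path `.func.gii` path.
#' @return Matrix, one map per row (maps x vertices).
#' @export
read_gifti_metric <- function(path) {
  arrays <- read_gifti_arrays(path)
  do.call(rbind, lapply(arrays, function(a) as.numeric(a$data)))
}

#' Write a mesh in the plain two-file array format
#'
#' Tab-separated text: a coordinates file (`x y z` per vertex, mm) and a
#' faces file (three 0-based vertex indices per triangle). A lowest-common-
#' denominator format for fixtures and interchange.
#'
#' @param mesh a [surface_mesh()].
#' @param coords_path,faces_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_mesh_arrays <- function(mesh, coords_path, faces_path) {
  utils::write.table(mesh$vertices, coords_path, sep = "\t",
                     row.names = FALSE, col.names = c("x", "y", "z"))
  utils::write.table(mesh$faces - 1L, faces_path, sep = "\t",
                     row.names = FALSE, col.names = c("v1", "v2", "v3"))
  invisible(c(coords_path, faces_path))
}

#' Read a mesh from the plain two-file array format
#'
#' @param coords_path,faces_path paths written by [write_mesh_arrays()].
#' @return A [surface_mesh()].
#' @export
read_mesh_arrays <- function(coords_path, faces_path) {
  v <- as.matrix(utils::read.table(coords_path, header = TRUE, sep = "\t"))
  f <- as.matrix(utils::read.table(faces_path, header = TRUE, sep = "\t"))
  surface_mesh(v, f + 1L)
}

#' Write a subjects-by-vertices metric matrix as TSV
#'
#' @param values numeric matrix or vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_tsv <- function(values, path) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  utils::write.table(values, path, sep = "\t", row.names = FALSE,
                     col.names = paste0("v", seq_len(ncol(values))))
  invisible(path)
}

#' Read a metric matrix written by [write_metric_tsv()]
#'
#' @param path input path.
#' @return Numeric matrix (maps x vertices).
#' @export
read_metric_tsv <- function(path) {
  unname(as.matrix(utils::read.table(path, header = TRUE, sep = "\t")))
}
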