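# Minimal GIFTI surface / per-vertex map I/O.
#
# GIFTI is XML; this reader/writer supports ASCII-encoded POINTSET + TRIANGLE
# arrays (surfaces) and 1-D scalar arrays (per-vertex maps), which covers the
# package's needs. Triangle indices are 0-based on disk (GIFTI convention)
# and 1-based in memory.

gifti_data_array <- function(doc, values, intent, datatype, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  fmt <- if (datatype == "NIFTI_TYPE_INT32") "%d" else "%.10g"
  txt <- paste(sprintf(fmt, values), collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

#' Write a surface mesh to GIFTI
#' @param mesh a `surface_mesh`.
#' @param path output `.gii` path.
#' @return the path, invisibly.
#' @export
write_surface <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  # row-major flattening of V x 3 / F x 3
  gifti_data_array(doc, as.numeric(t(mesh$vertices)),
                   "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64",
                   dim(mesh$vertices))
  gifti_data_array(doc, as.integer(t(mesh$faces) - 1L),
                   "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   dim(mesh$faces))
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(das, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("only ASCII-encoded GIFTI data arrays are supported, got ", enc)
    ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1L, function(i)
      as.integer(xml2::xml_attr(da, paste0("Dim", i))), 1L)
    txt <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
    vals <- scan(text = txt, quiet = TRUE)
    list(intent = xml2::xml_attr(da, "Intent"), dims = dims, values = vals)
  })
}

#' Read a surface mesh from GIFTI
#' @param path a `.gii` file with POINTSET and TRIANGLE arrays.
#' @return a `surface_mesh`.
#' @export
read_surface <- function(path) {
  arrs <- read_gifti_arrays(path)
  intents <- vapply(arrs, `[[`, "", "intent")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(ip) || is.na(it))
    stop("GIFTI file lacks POINTSET/TRIANGLE arrays: ", path)
  v <- matrix(arrs[[ip]]$values, ncol = 3L, byrow = TRUE)
  f <- matrix(as.integer(arrs[[it]]$values), ncol = 3L, byrow = TRUE) + 1L
  surface_mesh(v, f)
}

#' Write a per-vertex scalar map to GIFTI
#' @param values numeric vector, one value per vertex.
#' @param path output `.gii` path.
#' @return the path, invisibly.
#' @export
write_vertex_map <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  gifti_data_array(doc, as.numeric(values), "NIFTI_INTENT_NONE",
                   "NIFTI_TYPE_FLOAT64", length(values))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a per-vertex scalar map from GIFTI
#' @param path a `.gii` file with one 1-D data array.
#' @param mesh optional `surface_mesh`; if given, the vertex count is checked.
#' @return numeric vector.
#' @export
read_vertex_map <- function(path, mesh = NULL) {
  arrs <- read_gifti_arrays(path)
  sc <- Filter(function(a) a$intent != "NIFTI_INTENT_POINTSET" &&
                 a$intent != "NIFTI_INTENT_TRIANGLE", arrs)
  if (!length(sc)) stop("no scalar data array in ", path)
  vals <- sc[[1]]$values
  if (!is.null(mesh) && length(vals) != n_vertices(mesh))
    stop(sprintf("map has %d values but mesh has %d vertices",
                 length(vals), n_vertices(mesh)))
  vals
}
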