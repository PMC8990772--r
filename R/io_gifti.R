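# Minimal GIFTI (XML, ASCII-encoded) reader/writer: enough to round-trip
# surfaces (POINTSET + TRIANGLE), functional per-vertex maps, and label
# maps between runs. Base64/GZip encodings are not produced; reading is
# restricted to ASCII so files stay text and diffable.

gifti_data_array <- function(doc, intent, datatype, data, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  txt <- if (is.matrix(data))
    paste(apply(data, 1, paste, collapse = " "), collapse = "\n")
  else paste(data, collapse = "\n")
  xml2::xml_add_child(da, "Data", txt)
  da
}

#' Write a surface mesh as GIFTI
#'
#' @param mesh a [cortical_mesh()].
#' @param path output path (`.surf.gii`).
#' @return invisibly, the path.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_data_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                   mesh$vertices, dim(mesh$vertices))
  gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   mesh$faces - 1L, dim(mesh$faces))   # GIFTI is 0-based
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a per-vertex map (functional or label) as GIFTI
#'
#' @param values per-vertex numeric (functional) or integer (label) values;
#'   NA written as NaN.
#' @param path output path (`.func.gii` / `.label.gii`).
#' @param intent GIFTI intent string; labels use `"NIFTI_INTENT_LABEL"`.
#' @return invisibly, the path.
#' @export
write_gifti_map <- function(values, path, intent = "NIFTI_INTENT_NONE") {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  datatype <- if (intent == "NIFTI_INTENT_LABEL") "NIFTI_TYPE_INT32"
              else "NIFTI_TYPE_FLOAT32"
  vals <- if (datatype == "NIFTI_TYPE_INT32") as.integer(values)
          else ifelse(is.na(values), "NaN", format(values, digits = 17))
  gifti_data_array(doc, intent, datatype, vals, length(values))
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_gifti_numbers <- function(da) {
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  as.numeric(scan(text = txt, what = double(), quiet = TRUE))
}

#' Read a GIFTI file (ASCII encoding)
#'
#' Returns a [cortical_mesh()] when the file carries POINTSET + TRIANGLE
#' arrays, otherwise the per-vertex values of the first data array.
#'
#' @param path input path.
#' @return a `cortical_mesh` or a numeric vector.
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(das)) stop("no DataArray in GIFTI file")
  enc <- xml2::xml_attr(das, "Encoding")
  if (any(enc != "ASCII"))
    stop("only ASCII-encoded GIFTI is supported")
  intents <- xml2::xml_attr(das, "Intent")
  if ("NIFTI_INTENT_POINTSET" %in% intents &&
      "NIFTI_INTENT_TRIANGLE" %in% intents) {
    pv <- parse_gifti_numbers(das[[which(intents == "NIFTI_INTENT_POINTSET")]])
    fv <- parse_gifti_numbers(das[[which(intents == "NIFTI_INTENT_TRIANGLE")]])
    v <- matrix(pv, ncol = 3, byrow = TRUE)
    f <- matrix(as.integer(fv), ncol = 3, byrow = TRUE) + 1L
    return(cortical_mesh(v, f))
  }
  vals <- parse_gifti_numbers(das[[1]])
  vals[is.nan(vals)] <- NA_real_
  vals
}
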