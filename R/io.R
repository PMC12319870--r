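# GIFTI and NIfTI-1 I/O. Only the subset of each format needed here is
# supported: GIFTI surface/metric/label files with ASCII or (gzipped)
# base64 little-endian binary data, and single-file .nii volumes in the
# common numeric dtypes. These readers are deliberately strict: anything
# outside that subset errors rather than guessing.

.gifti_dtype <- function(dt) {
  switch(dt,
         NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
         NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
         NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
         NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
         stop("unsupported GIFTI datatype: ", dt))
}

.gifti_read_darray <- function(node) {
  at <- xml2::xml_attrs(node)
  dims <- as.integer(at[paste0("Dim", seq_len(as.integer(at[["Dimensionality"]])) - 1)])
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  enc <- at[["Encoding"]]
  if (enc == "ASCII") {
    vals <- scan(text = txt, quiet = TRUE)
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    dt <- .gifti_dtype(at[["DataType"]])
    endian <- if (identical(at[["Endian"]], "BigEndian")) "big" else "little"
    vals <- readBin(raw, dt$what, n = prod(dims), size = dt$size,
                    endian = endian, signed = dt$size > 1L)
  } else stop("unsupported GIFTI encoding: ", enc)
  order <- if (!is.na(at["ArrayIndexingOrder"])) at[["ArrayIndexingOrder"]]
           else "RowMajorOrder"
  if (length(dims) == 2L) {
    if (order == "RowMajorOrder")
      vals <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    else vals <- matrix(vals, nrow = dims[1], ncol = dims[2])
  }
  list(values = vals, intent = at[["Intent"]])
}

#' Read a GIFTI file
#'
#' Parses the DataArray elements of a `.gii` file (surface, metric/shape or
#' label). ASCII and (gzipped) base64 encodings are supported.
#'
#' @param path file path.
#' @return list of data arrays, each a list with `values` and `intent`.
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//DataArray")
  if (length(nodes) == 0) stop("no DataArray elements in ", path)
  lapply(nodes, .gifti_read_darray)
}

#' Read a GIFTI surface as a mesh
#'
#' @param path `.surf.gii` file with POINTSET and TRIANGLE arrays
#'   (triangles 0-based, as the format specifies).
#' @return an [fb_mesh()].
#' @export
read_gifti_surface <- function(path) {
  da <- read_gifti(path)
  pts <- Filter(function(d) identical(d$intent, "NIFTI_INTENT_POINTSET"), da)
  tri <- Filter(function(d) identical(d$intent, "NIFTI_INTENT_TRIANGLE"), da)
  if (length(pts) != 1 || length(tri) != 1)
    stop("surface file must hold one POINTSET and one TRIANGLE array")
  fb_mesh(pts[[1]]$values, tri[[1]]$values + 1L)
}

#' Read GIFTI metric/shape/label data
#'
#' @param path `.func.gii`, `.shape.gii` or `.label.gii` file.
#' @return numeric matrix, vertices x maps (single map: still a 1-column
#'   matrix).
#' @export
read_gifti_metric <- function(path) {
  da <- read_gifti(path)
  do.call(cbind, lapply(da, function(d) as.matrix(d$values)))
}

.gifti_skeleton <- function() {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "0")
  doc
}

.gifti_add_darray <- function(doc, values, intent, datatype) {
  dims <- if (is.matrix(values)) dim(values) else length(values)
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (d in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", d - 1), as.character(dims[d]))
  flat <- if (is.matrix(values)) as.vector(t(values)) else values
  txt <- if (datatype == "NIFTI_TYPE_INT32")
    paste(format(as.integer(flat), scientific = FALSE), collapse = " ")
  else paste(format(flat, digits = 9), collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  n <- as.integer(xml2::xml_attr(doc, "NumberOfDataArrays")) + 1L
  xml2::xml_set_attr(doc, "NumberOfDataArrays", as.character(n))
  invisible(doc)
}

#' Write a mesh as a GIFTI surface
#'
#' @param mesh an [fb_mesh()].
#' @param path output `.surf.gii` path. Triangles are written 0-based.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- .gifti_skeleton()
  .gifti_add_darray(doc, mesh$vertices, "NIFTI_INTENT_POINTSET",
                    "NIFTI_TYPE_FLOAT32")
  .gifti_add_darray(doc, mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                    "NIFTI_TYPE_INT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write per-vertex data as a GIFTI metric file
#'
#' @param values numeric vector (one map) or matrix (vertices x maps).
#' @param path output `.func.gii` / `.shape.gii` path.
#' @export
write_gifti_metric <- function(values, path) {
  doc <- .gifti_skeleton()
  values <- as.matrix(values)
  for (j in seq_len(ncol(values)))
    .gifti_add_darray(doc, values[, j], "NIFTI_INTENT_NONE",
                      "NIFTI_TYPE_FLOAT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write parcel labels as a GIFTI label file
#'
#' @param labels integer labels, one per vertex.
#' @param path output `.label.gii` path.
#' @export
write_gifti_label <- function(labels, path) {
  doc <- .gifti_skeleton()
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (k in sort(unique(labels)))
    xml2::xml_add_child(lt, "Label", Key = as.character(k),
                        sprintf("parcel_%d", k))
  .gifti_add_darray(doc, as.integer(labels), "NIFTI_INTENT_LABEL",
                    "NIFTI_TYPE_INT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- NIfTI-1 ----

.nifti_dtypes <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                      `4` = list(what = "integer", size = 2L, signed = TRUE),
                      `8` = list(what = "integer", size = 4L, signed = TRUE),
                      `16` = list(what = "double", size = 4L, signed = TRUE),
                      `64` = list(what = "double", size = 8L, signed = TRUE))

#' Write a voxel grid as a single-file NIfTI-1 volume
#'
#' Writes `values` (3D or 4D) as float32 with the grid affine in the sform.
#'
#' @param grid an `fb_voxel_grid` with non-NULL `values`.
#' @param path output `.nii` path.
#' @export
write_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "fb_voxel_grid"), !is.null(grid$values))
  dm <- dim(grid$values)
  nd <- length(dm)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348, 4)                                    # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(c(nd, dm, rep(1, 7 - nd)), 2)              # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0, 2)                                      # intent_code
  wi(16, 2); wi(32, 2); wi(0, 2)                # datatype=float32, bitpix, slice_start
  vox <- sqrt(sum(grid$affine[1:3, 1]^2))
  wf(c(1, rep(vox, 3), rep(1, 4)))              # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(2), con)               # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_duration, toffset
  wi(c(0, 0), 4)                                # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0, 1), 2)                                # qform_code=0, sform_code=1
  wf(rep(0, 6))                                 # quaternions/offsets
  wf(t(grid$affine[1:3, ]))                     # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.double(grid$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a single-file NIfTI-1 volume
#'
#' @param path `.nii` file path.
#' @return an `fb_voxel_grid` with `shape`, `affine` (sform, or a pixdim
#'   scaling if no sform), and `values` (3D or 4D array; scaling slope and
#'   intercept applied).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348) stop("not a NIfTI-1 file")
  }
  rd_i <- function(off, n, size)
    readBin(hdr[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = endian)
  rd_f <- function(off, n)
    readBin(hdr[(off + 1):(off + n * 4)], "double", n = n, size = 4,
            endian = endian)
  dim8 <- rd_i(40, 8, 2)
  nd <- dim8[1]
  dm <- dim8[2:(1 + nd)]
  datatype <- rd_i(70, 1, 2)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype)
  pixdim <- rd_f(76, 8)
  vox_offset <- rd_f(108, 1)
  scl <- rd_f(112, 2)
  sform_code <- rd_i(254, 1, 2)
  affine <- diag(4)
  if (sform_code > 0) {
    sr <- matrix(rd_f(280, 12), nrow = 3, byrow = TRUE)
    affine[1:3, ] <- sr
  } else diag(affine)[1:3] <- pixdim[2:4]
  seek(con, vox_offset)
  vals <- readBin(con, dt$what, n = prod(dm), size = dt$size,
                  signed = dt$signed, endian = endian)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  structure(list(shape = dm[1:3], affine = affine,
                 values = array(as.double(vals), dim = dm)),
            class = "fb_voxel_grid")
}

# ---- plain-text fixtures ----

#' Write a per-vertex scalar map as delimited text
#'
#' Two tab-separated columns, `vertex` (1-based) and `value`, with header.
#'
#' @param values numeric vector.
#' @param path output path.
#' @export
write_scalar_text <- function(values, path) {
  utils::write.table(data.frame(vertex = seq_along(values), value = values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-vertex scalar map written by [write_scalar_text()]
#'
#' @param path input path.
#' @return numeric vector ordered by vertex index.
#' @export
read_scalar_text <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  df$value[order(df$vertex)]
}
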