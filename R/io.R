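# Minimal GIFTI (.gii) reader/writer covering the surface, metric, and label
# files this package produces: XML with Base64-encoded little-endian arrays,
# row-major indexing order. Face indices are 0-based on disk.

gifti_encode <- function(x, type = c("float32", "int32")) {
  type <- match.arg(type)
  raw <- if (type == "float32") {
    writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
  } else {
    writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  }
  jsonlite::base64_enc(raw)
}

gifti_decode <- function(txt, type, n) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
  if (type == "NIFTI_TYPE_FLOAT32") {
    readBin(raw, "numeric", n = n, size = 4L, endian = "little")
  } else {
    readBin(raw, "integer", n = n, size = 4L, endian = "little")
  }
}

gifti_data_array <- function(x, intent, type) {
  x <- as.matrix(x)
  dims <- if (ncol(x) == 1L) {
    sprintf('Dimensionality="1" Dim0="%d"', nrow(x))
  } else {
    sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"', nrow(x), ncol(x))
  }
  dtype <- if (type == "float32") "NIFTI_TYPE_FLOAT32" else "NIFTI_TYPE_INT32"
  # row-major on disk
  payload <- gifti_encode(as.vector(t(x)), type)
  sprintf(
    paste0(
      '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
      '%s Encoding="Base64Binary" Endian="LittleEndian" ',
      'ExternalFileName="" ExternalFileOffset="">\n<Data>%s</Data>\n</DataArray>'
    ),
    intent, dtype, dims, payload
  )
}

gifti_write <- function(arrays, path) {
  body <- paste(arrays, collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="', length(arrays), '">\n',
    body, "\n</GIFTI>\n"
  )
  writeLines(xml, path)
}

gifti_read_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(das, function(da) {
    type <- xml2::xml_attr(da, "DataType")
    d0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    d1 <- xml2::xml_attr(da, "Dim1")
    d1 <- if (is.na(d1)) 1L else as.integer(d1)
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    vals <- gifti_decode(txt, type, d0 * d1)
    m <- matrix(vals, nrow = d0, ncol = d1, byrow = TRUE)
    list(intent = xml2::xml_attr(da, "Intent"), data = m)
  })
}

#' Write a surface to disk
#'
#' GIFTI `.surf.gii` (coordinates + triangles, float32/int32, 0-based face
#' indices) or Wavefront OBJ, chosen by file extension.
#'
#' @param surface a [cortical_surface].
#' @param path output path ending in `.gii` or `.obj`.
#' @export
write_surface <- function(surface, path) {
  if (grepl("\\.gii$", path)) {
    gifti_write(c(
      gifti_data_array(surface$vertices, "NIFTI_INTENT_POINTSET", "float32"),
      gifti_data_array(surface$faces - 1L, "NIFTI_INTENT_TRIANGLE", "int32")
    ), path)
  } else if (grepl("\\.obj$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(
      "v %.17g %.17g %.17g",
      surface$vertices[, 1], surface$vertices[, 2], surface$vertices[, 3]
    ), con)
    writeLines(sprintf(
      "f %d %d %d", surface$faces[, 1], surface$faces[, 2], surface$faces[, 3]
    ), con)
  } else {
    stop("unsupported surface format: ", path)
  }
  invisible(path)
}

#' Read a surface from disk
#'
#' Reads GIFTI `.surf.gii` or OBJ files written by [write_surface()]. The
#' spherical projection is recomputed by normalising centred coordinates.
#'
#' @param path path to a `.gii` or `.obj` file.
#' @return A [cortical_surface].
#' @export
read_surface <- function(path) {
  if (grepl("\\.gii$", path)) {
    arrs <- gifti_read_arrays(path)
    pts <- NULL
    tri <- NULL
    for (a in arrs) {
      if (a$intent == "NIFTI_INTENT_POINTSET") pts <- a$data
      if (a$intent == "NIFTI_INTENT_TRIANGLE") tri <- a$data
    }
    if (is.null(pts) || is.null(tri)) stop("GIFTI surface needs POINTSET and TRIANGLE arrays")
    cortical_surface(pts, tri + 1L)
  } else if (grepl("\\.obj$", path)) {
    lns <- readLines(path)
    vl <- lns[startsWith(lns, "v ")]
    fl <- lns[startsWith(lns, "f ")]
    pts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
    tri <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) as.integer(p[2:4])))
    cortical_surface(pts, tri)
  } else {
    stop("unsupported surface format: ", path)
  }
}

#' Write a scalar or label map
#'
#' GIFTI `.func.gii`/`.shape.gii` (float32), `.label.gii` (int32), or CSV with
#' one value per vertex and a header naming the map.
#'
#' @param values numeric (or integer for labels) vector of length V.
#' @param path output path (`.gii` or `.csv`).
#' @param name map name used as the CSV header.
#' @export
write_map <- function(values, path, name = "map") {
  if (grepl("\\.label\\.gii$", path)) {
    gifti_write(gifti_data_array(as.integer(values), "NIFTI_INTENT_LABEL", "int32"), path)
  } else if (grepl("\\.gii$", path)) {
    gifti_write(gifti_data_array(as.numeric(values), "NIFTI_INTENT_NONE", "float32"), path)
  } else if (grepl("\\.csv$", path)) {
    df <- data.frame(x = values)
    names(df) <- name
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("unsupported map format: ", path)
  }
  invisible(path)
}

#' Read a scalar or label map
#'
#' @param path path to a `.gii` or `.csv` map.
#' @param surface optional [cortical_surface]; if given, the vertex count is
#'   checked and a mismatch is an error naming both counts.
#' @return numeric (or integer) vector; for CSV the map name is attached as
#'   the `name` attribute.
#' @export
read_map <- function(path, surface = NULL) {
  if (grepl("\\.gii$", path)) {
    arrs <- gifti_read_arrays(path)
    vals <- drop(arrs[[1]]$data)
  } else if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path)
    vals <- df[[1]]
    attr(vals, "name") <- names(df)[1]
  } else {
    stop("unsupported map format: ", path)
  }
  if (!is.null(surface) && length(vals) != n_vertices(surface)) {
    stop(sprintf(
      "map has %d values but surface has %d vertices",
      length(vals), n_vertices(surface)
    ))
  }
  vals
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated gene-set format: set name, description, then member
#' genes, one set per line.
#'
#' @param path path to a `.gmt` file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lns <- readLines(path)
  lns <- lns[nzchar(lns)]
  out <- lapply(lns, function(l) {
    p <- strsplit(l, "\t", fixed = TRUE)[[1]]
    p[-(1:2)]
  })
  names(out) <- vapply(lns, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lns <- mapply(function(nm, dsc, genes) {
    paste(c(nm, dsc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lns, path)
  invisible(path)
}

#' Write donor expression data as TSV
#'
#' Writes `expr.tsv` (genes x samples, row names = gene ids) and
#' `samples.csv` (sample_id, x, y, z, donor, sex) into a directory, the
#' on-disk layout consumed by [read_donor_dir()].
#'
#' @param donor a `donor_expression` object (see [sample_donors()]).
#' @param dir output directory (created if needed).
#' @export
write_donor <- function(donor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- as.data.frame(donor$expr)
  colnames(expr) <- donor$sample_ids
  utils::write.table(
    cbind(gene = donor$gene_ids, expr),
    file.path(dir, "expr.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.csv(data.frame(
    sample_id = donor$sample_ids,
    x = donor$sample_coords[, 1],
    y = donor$sample_coords[, 2],
    z = donor$sample_coords[, 3],
    donor = donor$donor_id,
    sex = donor$sex
  ), file.path(dir, "samples.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read one donor's expression data from a directory
#'
#' @param dir directory containing `expr.tsv` and `samples.csv` as written by
#'   [write_donor()].
#' @return A `donor_expression` object.
#' @export
read_donor_dir <- function(dir) {
  expr <- utils::read.delim(file.path(dir, "expr.tsv"), check.names = FALSE)
  genes <- expr[[1]]
  em <- as.matrix(expr[, -1, drop = FALSE])
  smp <- utils::read.csv(file.path(dir, "samples.csv"))
  donor_expression(
    donor_id = as.character(smp$donor[1]),
    sex = as.character(smp$sex[1]),
    sample_coords = as.matrix(smp[, c("x", "y", "z")]),
    expr = em,
    gene_ids = as.character(genes),
    sample_ids = as.character(smp$sample_id)
  )
}
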