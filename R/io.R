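#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports `.nii`/`.nii.gz` (via RNifti) and MetaImage `.mha`/`.mhd`.
#' Only 3D scalar, axis-aligned volumes are accepted.
#'
#' @param path Path to the file.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop("expected a 3D volume, got ", length(dim(arr)), "D data")
    attributes(arr) <- list(dim = dim(arr))
    m <- RNifti::xform(img)
    scalar_volume(arr, spacing = RNifti::pixdim(img)[1:3],
                  origin = m[1:3, 4])
  } else {
    read_metaimage(path)
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The format follows the file extension. Values, spacing, and origin
#' round-trip bit-comparably within the same format.
#'
#' @param vol A [scalar_volume()].
#' @param path Output path ending in `.nii`, `.nii.gz`, `.mha`, or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(4); diag(m)[1:3] <- vol$spacing; m[1:3, 4] <- vol$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    write_metaimage(vol, path)
  }
  invisible(path)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("metaimage")
  stop("unrecognised volume format: ", path,
       " (expected .nii, .nii.gz, .mha, or .mhd)")
}

# ---- MetaImage (.mha single-file / .mhd header + .raw) ----

mha_types <- c(MET_UCHAR = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_INT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mha_sizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "\\s*=\\s*")[[1L]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[1L]]] <- kv[2L]
    if (kv[1L] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L) stop("expected a 3D volume, got ", ndims, "D data")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  if (!type %in% names(mha_types)) stop("unsupported ElementType: ", type)
  if (identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE"))
    stop("compressed MetaImage data is not supported")
  swap <- identical(toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE"), "TRUE")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, mha_types[[type]], n = n, size = mha_sizes[[type]],
                   endian = if (swap) "big" else "little",
                   signed = !type %in% c("MET_UCHAR", "MET_USHORT"))
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("missing data file: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, mha_types[[type]], n = n, size = mha_sizes[[type]],
                   endian = if (swap) "big" else "little",
                   signed = !type %in% c("MET_UCHAR", "MET_USHORT"))
  }
  if (length(raw) != n) stop("truncated MetaImage data: ", path)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1L]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1L]])
  scalar_volume(array(as.double(raw), dims), spacing, origin)
}

write_metaimage <- function(vol, path) {
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) sub("\\.mhd$", ".raw", basename(path),
                           ignore.case = TRUE) else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(vol$values), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                    collapse = " ")),
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (mhd) {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.vector(vol$values), rcon, size = 8L, endian = "little")
  } else {
    writeBin(as.vector(vol$values), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Mesh I/O: STL (ASCII + binary read, ASCII write), PLY, VTP ----

#' Read a triangular surface mesh
#'
#' Supports STL (ASCII or binary; duplicate vertices merged within 1e-6 mm),
#' PLY (ASCII), and VTK PolyData `.vtp` (XML, ASCII buffers). PLY faces with
#' more than 3 vertices are fan-triangulated when `triangulate = TRUE`,
#' otherwise rejected.
#'
#' @param path Path to `.stl`, `.ply`, or `.vtp` file.
#' @param triangulate Fan-triangulate polygonal faces (default `TRUE`).
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, triangulate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path, triangulate),
         vtp = read_vtp(path, triangulate),
         stop("unrecognised mesh format: ", path))
}

#' Write a triangular surface mesh
#'
#' Format follows the extension: ASCII STL, ASCII PLY, or XML `.vtp`.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path ending in `.stl`, `.ply`, or `.vtp`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         vtp = write_vtp(mesh, path),
         stop("unrecognised mesh format: ", path))
  invisible(path)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5L)
  if (identical(rawToChar(head), "solid")) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed ASCII STL: ", path)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    verts <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (ntri < 1L) stop("empty STL mesh: ", path)
    rec <- readBin(con, "numeric", n = ntri * 12L, size = 4L,
                   endian = "little")
    # interleaved attribute bytes: re-read record-wise
    close(con); on.exit()
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", n = 84L)
    verts <- matrix(0, ntri * 3L, 3L)
    for (t in seq_len(ntri)) {
      vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)
      verts[(3 * t - 2):(3 * t), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
  }
  ntri <- nrow(verts) / 3L
  if (ntri < 1L) stop("empty STL mesh: ", path)
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  merge_duplicate_vertices(verts, faces, tol = 1e-6)
}

write_stl <- function(mesh, path) {
  fn <- face_normals(mesh)$normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vesselmesh", con)
  v <- mesh$vertices; f <- mesh$faces
  for (t in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", fn[t, 1], fn[t, 2], fn[t, 3]),
      "    outer loop",
      sprintf("      vertex %.17g %.17g %.17g",
              v[f[t, ], 1], v[f[t, ], 2], v[f[t, ], 3]),
      "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid vesselmesh", con)
}

read_ply <- function(path, triangulate) {
  txt <- readLines(path, warn = FALSE)
  if (!identical(txt[1L], "ply")) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", txt[1:5])))
    stop("only ASCII PLY is supported: ", path)
  endh <- match("end_header", txt)
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", txt, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", txt, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf) || nv == 0L || nf == 0L)
    stop("empty or malformed PLY mesh: ", path)
  vl <- txt[(endh + 1L):(endh + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[1:3])))
  fl <- txt[(endh + nv + 1L):(endh + nv + nf)]
  faces <- list()
  for (line in fl) {
    x <- as.integer(strsplit(trimws(line), "\\s+")[[1L]])
    k <- x[1L]; idx <- x[2:(k + 1L)] + 1L
    if (k == 3L) {
      faces[[length(faces) + 1L]] <- idx
    } else if (triangulate) {
      for (j in 2:(k - 1L))
        faces[[length(faces) + 1L]] <- c(idx[1L], idx[j], idx[j + 1L])
    } else {
      stop("non-triangular PLY face and triangulate = FALSE")
    }
  }
  triangle_mesh(verts, do.call(rbind, faces), validate = FALSE)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

read_vtp <- function(path, triangulate) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  coords <- as.numeric(strsplit(trimws(xml2::xml_text(pts)), "\\s+")[[1L]])
  verts <- matrix(coords, ncol = 3L, byrow = TRUE)
  conn <- as.integer(strsplit(trimws(xml2::xml_text(xml2::xml_find_first(
    piece, ".//Polys/DataArray[@Name='connectivity']"))), "\\s+")[[1L]])
  offs <- as.integer(strsplit(trimws(xml2::xml_text(xml2::xml_find_first(
    piece, ".//Polys/DataArray[@Name='offsets']"))), "\\s+")[[1L]])
  faces <- list()
  start <- 1L
  for (o in offs) {
    idx <- conn[start:o] + 1L
    k <- length(idx)
    if (k == 3L) {
      faces[[length(faces) + 1L]] <- idx
    } else if (triangulate) {
      for (j in 2:(k - 1L))
        faces[[length(faces) + 1L]] <- c(idx[1L], idx[j], idx[j + 1L])
    } else {
      stop("non-triangular VTP cell and triangulate = FALSE")
    }
    start <- o + 1L
  }
  if (length(faces) == 0L) stop("empty VTP mesh: ", path)
  triangle_mesh(verts, do.call(rbind, faces), validate = FALSE)
}

write_vtp <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  pts <- paste(sprintf("%.17g", t(mesh$vertices)), collapse = " ")
  conn <- paste(t(mesh$faces) - 1L, collapse = " ")
  offs <- paste(seq_len(nf) * 3L, collapse = " ")
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    '  <PolyData>\n',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfPolys="%d">\n', nv, nf),
    '      <Points>\n',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    pts, '</DataArray>\n',
    '      </Points>\n',
    '      <Polys>\n',
    '        <DataArray type="Int32" Name="connectivity" format="ascii">',
    conn, '</DataArray>\n',
    '        <DataArray type="Int32" Name="offsets" format="ascii">',
    offs, '</DataArray>\n',
    '      </Polys>\n',
    '    </Piece>\n',
    '  </PolyData>\n',
    '</VTKFile>\n')
  writeLines(xml, path, sep = "")
}
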