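#' Read a 3D scalar volume
#'
#' NIfTI (`.nii`, `.nii.gz`, via RNifti) and MetaImage (`.mha`, or `.mhd`
#' with a separate raw file) are supported. The image-to-world transform is
#' converted to the package convention (RAS mm, voxel centres at
#' half-integer continuous coordinates, see [scalar_volume()]).
#'
#' @param path volume file.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         nii = read_volume_nifti(path),
         mha = , mhd = read_volume_mha(path),
         stopf("unsupported volume format '.%s'", ext))
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  dat <- as.array(img)
  if (length(dim(dat)) != 3L) stopf("expected a 3D volume in '%s'", path)
  dat <- array(as.numeric(dat), dim(dat))  # strip NIfTI attributes
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2L, spacing, "/")
  # NIfTI maps 0-based index -> voxel centre; our origin is the corner
  centre0 <- aff[1:3, 4L]
  origin <- centre0 - as.numeric(direction %*% (0.5 * spacing))
  scalar_volume(dat, spacing, origin, direction)
}

read_volume_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stopf("parse error in '%s': no ElementDataFile key", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stopf("parse error in '%s': bad header line '%s'", path, line)
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(split_fields(hdr$DimSize))
  if (length(dims) != 3L) stopf("'%s': only 3D MetaImage supported", path)
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(split_fields(hdr$ElementSpacing)) else c(1, 1, 1)
  offset <- if (!is.null(hdr$Offset)) as.numeric(split_fields(hdr$Offset)) else c(0, 0, 0)
  direction <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(split_fields(hdr$TransformMatrix)), 3L, 3L) else diag(3)
  type <- hdr$ElementType
  n <- prod(dims)
  dat <- switch(type,
                "MET_FLOAT" = readBin(con, "double", n, size = 4L, endian = "little"),
                "MET_DOUBLE" = readBin(con, "double", n, size = 8L, endian = "little"),
                "MET_UCHAR" = as.numeric(readBin(con, "integer", n, size = 1L,
                                                 signed = FALSE, endian = "little")),
                "MET_SHORT" = as.numeric(readBin(con, "integer", n, size = 2L,
                                                 signed = TRUE, endian = "little")),
                stopf("'%s': unsupported ElementType %s", path, type))
  if (length(dat) != n) stopf("'%s': truncated pixel data", path)
  # MetaImage Offset is the centre of the first voxel
  origin <- offset - as.numeric(direction %*% (0.5 * spacing))
  scalar_volume(array(dat, dims), spacing, origin, direction)
}

#' Write a 3D scalar volume
#'
#' Formats as in [read_volume()]. MetaImage is written as a single `.mha`
#' with local raw `MET_FLOAT` data; NIfTI carries the transform in its
#' qform.
#'
#' @param volume a [scalar_volume()].
#' @param path output file (`.nii`, `.nii.gz` or `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    centre0 <- volume$origin + as.numeric(volume$direction %*% (0.5 * volume$spacing))
    aff <- rbind(cbind(volume$direction %*% diag(volume$spacing), centre0),
                 c(0, 0, 0, 1))
    img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (ext == "mha") {
    offset <- volume$origin + as.numeric(volume$direction %*% (0.5 * volume$spacing))
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             paste("TransformMatrix =", paste(sprintf("%.17g", volume$direction),
                                              collapse = " ")),
             paste("Offset =", paste(sprintf("%.17g", offset), collapse = " ")),
             paste("ElementSpacing =", paste(sprintf("%.17g", volume$spacing),
                                             collapse = " ")),
             paste("DimSize =", paste(dim(volume$data), collapse = " ")),
             "ElementType = MET_FLOAT", "ElementDataFile = LOCAL")
    writeLines(hdr, con)
    writeBin(as.numeric(volume$data), con, size = 4L, endian = "little")
  } else {
    stopf("unsupported volume format '.%s'", ext)
  }
  invisible(path)
}
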