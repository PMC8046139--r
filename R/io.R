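#' Read FSL-style b-values and b-vectors
#'
#' b-values are whitespace-delimited scalars; b-vectors may be stored as
#' 3 rows x n columns (FSL convention) or n rows x 3 columns — the layout
#' is auto-detected from the shape.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @return List with `bvals` (numeric vector, ms/um^2 if stored in s/mm^2
#'   divide by 1000 yourself) and `bvecs` (n x 3 matrix, rows renormalised
#'   to unit length where nonzero).
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  m <- as.matrix(read.table(bvec_path))
  if (nrow(m) == 3 && ncol(m) != 3) {
    m <- t(m)
  } else if (ncol(m) != 3) {
    stop("bvecs must be 3 x n or n x 3", call. = FALSE)
  }
  if (nrow(m) != length(bvals)) {
    stop("bvals and bvecs disagree on the number of volumes", call. = FALSE)
  }
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, ] / nrm[nz]
  dimnames(m) <- NULL
  list(bvals = bvals, bvecs = m)
}

#' Write a 3-D/4-D map as NIfTI
#'
#' Thin wrapper over [RNifti::writeNifti()] that stamps the voxel
#' dimensions.
#'
#' @param arr Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_dim Voxel size (mm), length 3.
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(arr, path, voxel_dim = c(2.5, 2.5, 2.5)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_dim, rep(1, length(dim(arr)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return List with `data` (array) and `voxel_dim`.
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxel_dim = RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))])
}

#' Read / write MRtrix TCK streamline files
#'
#' Minimal reader and writer for the TCK format: a text header terminated
#' by `END`, then little-endian float32 triplets with NaN triplets
#' separating streamlines and an Inf triplet terminating the file.
#' Coordinates are in scanner mm space.
#'
#' @param path File path.
#' @return `read_tck`: list of m x 3 matrices.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("mrtrix tracks", magic)) stop("not a TCK file", call. = FALSE)
  offset <- NULL
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || grepl("^END", line)) break
    if (grepl("^file:", line)) {
      offset <- as.integer(sub(".*\\. ", "", line))
    }
    if (grepl("^datatype:", line)) {
      datatype <- trimws(sub("datatype:", "", line))
    }
  }
  if (datatype != "Float32LE") {
    stop("only Float32LE TCK data supported", call. = FALSE)
  }
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  breaks <- which(is.nan(m[, 1]) | is.infinite(m[, 1]))
  out <- list()
  start <- 1
  for (b in breaks) {
    if (b > start) out[[length(out) + 1]] <- m[start:(b - 1), , drop = FALSE]
    start <- b + 1
    if (is.infinite(m[b, 1])) break
  }
  out
}

#' @rdname read_tck
#' @param streamlines List of m x 3 matrices.
#' @return `write_tck`: the path, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  header <- c("mrtrix tracks", "datatype: Float32LE",
              sprintf("count: %d", length(streamlines)))
  # compute the data offset: header + the "file" line + END + newlines
  probe <- function(off) sprintf("file: . %d", off)
  base_len <- sum(nchar(header)) + length(header) + nchar("END") + 1
  off <- base_len + nchar(probe(10000)) + 1
  header <- c(header, probe(off), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  pad <- off - seek(con)
  if (pad > 0) writeBin(raw(pad), con)
  for (s in streamlines) {
    writeBin(as.vector(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Write an along-tract profile as TSV
#'
#' @param profile A `tract_profile` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  flat <- dplyr::select(profile, -dplyr::any_of("series"))
  series <- dplyr::bind_rows(profile$series) |>
    tidyr::pivot_wider(names_from = "shell", values_from = "sbar",
                       names_prefix = "sbar_shell", id_cols = "segment",
                       unused_fn = list())
  flat <- dplyr::left_join(flat, series, by = "segment")
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
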