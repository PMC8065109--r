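#' Contact map objects
#'
#' A `contact_map` holds one chromosome's square, symmetric, non-negative
#' intra-chromosomal Hi-C contact matrix together with its bin resolution and
#' balancing state. Bin `i` (0-based) covers the half-open genomic interval
#' `[i * resolution, (i + 1) * resolution)`.
#'
#' @param matrix square numeric matrix of contact frequencies.
#' @param chrom chromosome label.
#' @param resolution bin size in base pairs (default 10 kb).
#' @param balanced logical; has matrix balancing been applied?
#' @return An object of class `contact_map` with fields `matrix`, `chrom`,
#'   `resolution`, `balanced` and `bad_bins` (0-based indices of bins whose
#'   row sum is zero).
#' @examples
#' m <- matrix(c(4, 1, 1, 1), 2, 2)
#' cm <- contact_map(m, chrom = "chrS", resolution = 1e4)
#' cm$bad_bins
#' @export
contact_map <- function(matrix, chrom = "chr1", resolution = 10000,
                        balanced = FALSE) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("contact matrix must be square")
  if (resolution <= 0) stop("resolution must be positive")
  storage.mode(matrix) <- "double"
  obj <- structure(list(
    matrix = matrix, chrom = as.character(chrom),
    resolution = as.numeric(resolution), balanced = isTRUE(balanced),
    bad_bins = integer(0)
  ), class = "contact_map")
  obj$bad_bins <- which(rowSums(obj$matrix, na.rm = TRUE) == 0) - 1L
  obj
}

#' @export
print.contact_map <- function(x, ...) {
  n <- nrow(x$matrix)
  cat(sprintf("contact_map: %s, %d bins @ %g bp (%.2f Mb)\n",
              x$chrom, n, x$resolution, n * x$resolution / 1e6))
  cat(sprintf("  balanced: %s | bad bins: %d | total signal: %.4g\n",
              x$balanced, length(x$bad_bins), sum(x$matrix)))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$matrix)

#' Clean a contact map
#'
#' Replaces non-finite and negative entries by zero, symmetrizes the matrix
#' as `(M + t(M)) / 2`, and records zero-sum rows as bad bins. The result
#' always satisfies the `contact_map` invariants for any finite input.
#'
#' @param cm a [contact_map].
#' @return A cleaned `contact_map`.
#' @export
clean <- function(cm) UseMethod("clean")

#' @export
clean.contact_map <- function(cm) {
  m <- cm$matrix
  m[!is.finite(m)] <- 0
  m[m < 0] <- 0
  m <- (m + t(m)) / 2
  out <- contact_map(m, cm$chrom, cm$resolution, cm$balanced)
  out
}

#' Knight-Ruiz style matrix balancing
#'
#' Rescales a symmetric non-negative contact matrix as `D %*% A %*% D` with a
#' positive diagonal `D` so that all unmasked row sums are equal (the
#' equalized-marginal contract of Knight-Ruiz normalization). Rows with zero
#' marginal are masked out before balancing and restored as zero
#' rows/columns. The implementation is a symmetric fixed-point iteration
#' `d <- d / sqrt(rowsum / mean(rowsum))`, run until the relative spread of
#' unmasked row sums is below `tol`.
#'
#' @param cm a [contact_map]; the matrix must be symmetric and non-negative.
#' @param tol relative row-sum tolerance for convergence.
#' @param max_iter iteration budget; exceeded budget is an error that names
#'   the last residual.
#' @return A balanced `contact_map` (`balanced = TRUE`).
#' @examples
#' cm <- contact_map(matrix(c(4, 1, 1, 1), 2, 2))
#' b <- kr_balance(cm)
#' rowSums(b$matrix)
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 1000) {
  m <- cm$matrix
  if (any(m < 0)) stop("matrix must be non-negative")
  if (max(abs(m - t(m))) > 1e-6 * max(1, max(abs(m))))
    stop("matrix must be symmetric; run clean() first")
  keep <- rowSums(m) > 0
  out <- m * 0
  if (!any(keep)) {
    res <- contact_map(out, cm$chrom, cm$resolution, balanced = TRUE)
    return(res)
  }
  a <- m[keep, keep, drop = FALSE]
  d <- rep(1, nrow(a))
  resid <- Inf
  for (it in seq_len(max_iter)) {
    r <- as.vector(a %*% d) * d  # row sums of D A D
    mr <- mean(r)
    resid <- max(abs(r / mr - 1))
    if (resid < tol) break
    # guard masked-to-nonzero degeneracies: rows can't reach exactly zero here
    d <- d / sqrt(r / mr)
    if (it == max_iter)
      stop(sprintf("KR balancing did not converge in %d iterations (residual %.3g)",
                   max_iter, resid))
  }
  out[keep, keep] <- a * outer(d, d)
  contact_map(out, cm$chrom, cm$resolution, balanced = TRUE)
}

# ---- input / output ---------------------------------------------------------

.dense_binary_magic <- "VHCB"

#' Read and write contact maps
#'
#' Three on-disk dialects are supported: `dense-text` (whitespace-separated
#' square matrix), `dense-binary` (a self-describing container holding the
#' matrix together with its chromosome label and resolution), and `cooler`
#' (single-resolution `.cool`, an HDF5 file; accessed through the `h5py`
#' Python library, which must be importable by the `python` on `PATH`).
#'
#' Loading replaces NaN entries by zero (the count is recorded in the
#' `n_nonfinite` attribute of the returned object) and validates squareness.
#'
#' @param path file path.
#' @param format one of `"cooler"`, `"dense-text"`, `"dense-binary"`.
#' @param chrom chromosome label (required for cooler; stored otherwise).
#' @param resolution bin size in bp; must match the file's binning for
#'   cooler input.
#' @param cm a [contact_map] to write.
#' @return `load_contact_map` returns a [contact_map];
#'   `write_contact_map` returns `path` invisibly.
#' @export
load_contact_map <- function(path, format = c("dense-text", "dense-binary", "cooler"),
                             chrom = "chr1", resolution = 10000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense-text") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) stop("dense input is not square")
  } else if (format == "dense-binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 4, useBytes = TRUE)
    if (!identical(magic, .dense_binary_magic)) stop("not a dense-binary contact file")
    nc <- readBin(con, "integer", 1)
    chrom <- readChar(con, nc, useBytes = TRUE)
    resolution <- readBin(con, "double", 1)
    n <- readBin(con, "integer", 1)
    m <- matrix(readBin(con, "double", n * n), n, n)
  } else {
    m <- .read_cool_dense(path, chrom, resolution)
  }
  nbad <- sum(!is.finite(m))
  m[!is.finite(m)] <- 0
  out <- contact_map(m, chrom, resolution)
  attr(out, "n_nonfinite") <- nbad
  out
}

#' @rdname load_contact_map
#' @export
write_contact_map <- function(cm, path,
                              format = c("dense-text", "dense-binary", "cooler")) {
  format <- match.arg(format)
  if (format == "dense-text") {
    utils::write.table(cm$matrix, path, row.names = FALSE, col.names = FALSE)
  } else if (format == "dense-binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(.dense_binary_magic, con, eos = NULL)
    writeBin(nchar(cm$chrom), con)
    writeChar(cm$chrom, con, eos = NULL)
    writeBin(as.double(cm$resolution), con)
    writeBin(as.integer(nrow(cm$matrix)), con)
    writeBin(as.double(cm$matrix), con)
  } else {
    .write_cool(cm, path)
  }
  invisible(path)
}

# ---- cooler access via python/h5py -----------------------------------------

.python_bin <- function() {
  p <- Sys.which("python")
  if (p == "") p <- Sys.which("python3")
  if (p == "") stop("cooler support needs a `python` with h5py on PATH")
  p
}

.run_python <- function(code, args = character()) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  out <- suppressWarnings(
    system2(.python_bin(), c(f, args), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python helper failed: ", paste(out, collapse = "\n"))
  out
}

.read_cool_dense <- function(path, chrom, resolution) {
  code <- '
import sys, h5py
import numpy as np
path, chrom, res, out = sys.argv[1], sys.argv[2], float(sys.argv[3]), sys.argv[4]
f = h5py.File(path, "r")
names = [n.decode() if isinstance(n, bytes) else str(n) for n in f["chroms/name"][:]]
if chrom not in names:
    sys.stderr.write("chromosome not found: %s\\n" % chrom)
    sys.exit(3)
binsize = float(f.attrs.get("bin-size", 0))
if binsize and abs(binsize - res) > 0.5:
    sys.stderr.write("resolution mismatch: file has %g\\n" % binsize)
    sys.exit(4)
chrom_ids = f["bins/chrom"][:]
ci = names.index(chrom)
mask = chrom_ids == ci
bins = np.where(mask)[0]
lo, hi = bins.min(), bins.max() + 1
b1 = f["pixels/bin1_id"][:]
b2 = f["pixels/bin2_id"][:]
v = f["pixels/count"][:]
sel = (b1 >= lo) & (b1 < hi) & (b2 >= lo) & (b2 < hi)
n = hi - lo
m = np.zeros((n, n))
i = b1[sel] - lo; j = b2[sel] - lo
m[i, j] = v[sel]; m[j, i] = v[sel]
np.savetxt(out, m)
'
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  tryCatch(.run_python(code, c(path, chrom, format(resolution), tmp)),
           error = function(e) {
             if (grepl("chromosome not found", conditionMessage(e)))
               stop("chromosome not found: ", chrom, call. = FALSE)
             stop(e)
           })
  m <- as.matrix(utils::read.table(tmp, header = FALSE))
  dimnames(m) <- NULL
  m
}

.write_cool <- function(cm, path) {
  # upper-triangle COO pixels, single resolution
  m <- cm$matrix
  n <- nrow(m)
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  utils::write.table(
    data.frame(b1 = idx[, 1] - 1L, b2 = idx[, 2] - 1L, v = m[idx]),
    tmp, row.names = FALSE, col.names = FALSE)
  code <- '
import sys, h5py
import numpy as np
src, path, chrom, res, n = sys.argv[1], sys.argv[2], sys.argv[3], float(sys.argv[4]), int(sys.argv[5])
px = np.loadtxt(src, ndmin=2)
if px.size == 0:
    px = np.zeros((0, 3))
order = np.lexsort((px[:, 1], px[:, 0]))
px = px[order]
f = h5py.File(path, "w")
f.attrs["format"] = "HDF5::Cooler"
f.attrs["format-version"] = 3
f.attrs["bin-size"] = int(res)
f.attrs["nbins"] = n
g = f.create_group("chroms")
g.create_dataset("name", data=np.array([chrom.encode()]))
g.create_dataset("length", data=np.array([int(n * res)]))
g = f.create_group("bins")
g.create_dataset("chrom", data=np.zeros(n, dtype="i4"))
g.create_dataset("start", data=(np.arange(n) * res).astype("i8"))
g.create_dataset("end", data=((np.arange(n) + 1) * res).astype("i8"))
g = f.create_group("pixels")
g.create_dataset("bin1_id", data=px[:, 0].astype("i8"))
g.create_dataset("bin2_id", data=px[:, 1].astype("i8"))
g.create_dataset("count", data=px[:, 2])
offsets = np.searchsorted(px[:, 0], np.arange(n + 1))
g = f.create_group("indexes")
g.create_dataset("bin1_offset", data=offsets.astype("i8"))
g.create_dataset("chrom_offset", data=np.array([0, n], dtype="i8"))
f.close()
'
  .run_python(code, c(tmp, path, cm$chrom, format(cm$resolution), nrow(m)))
  invisible(path)
}
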