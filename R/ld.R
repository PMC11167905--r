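#' LD correlation matrices for cis regions
#'
#' An `ld_matrix` is a plain numeric correlation matrix (entries in
#' `[-1, 1]`, unit diagonal, symmetric) whose row and column names are SNP
#' identifiers. It drives both LD clumping (through its squared entries,
#' the familiar r-squared) and the simulation of LD-correlated summary
#' statistics.
#'
#' @param r Square numeric matrix of pairwise correlations.
#' @param snp_ids Character vector of SNP identifiers, one per row.
#' @return A matrix of class `ld_matrix` with `snp_ids` as dimnames.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(r)))
  if (length(snp_ids) != nrow(r)) stop("snp_ids length must match matrix size")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in LD matrix")
  if (max(abs(r - t(r))) > 1e-12) stop("LD matrix must be symmetric (1e-12)")
  if (max(abs(diag(r) - 1)) > 1e-12) stop("LD matrix must have unit diagonal")
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("LD matrix is not positive semi-definite; repair it with repair_ld()")
  }
  dimnames(r) <- list(snp_ids, snp_ids)
  class(r) <- c("ld_matrix", "matrix", "array")
  r
}

#' Construct an AR-1 (first-order autoregressive) LD matrix
#'
#' The correlation between SNPs i and j is `rho^|i-j|`, a standard stylized
#' model of LD decay along a chromosome: adjacent SNPs are the most
#' correlated and correlation decays geometrically with map distance.
#'
#' @param m Number of SNPs (>= 1).
#' @param rho AR-1 decay parameter in `[0, 1)`. `rho = 0` gives linkage
#'   equilibrium (identity matrix).
#' @param snp_ids Optional SNP identifiers; defaults to `snp01, snp02, ...`.
#' @return An [ld_matrix()].
#' @examples
#' r <- make_ld_matrix(3, 0.9)
#' r[1, 3]      # 0.81
#' r[1, 3]^2    # r-squared 0.6561
#' @export
make_ld_matrix <- function(m, rho, snp_ids = NULL) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1)
  m <- as.integer(m)
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)")
  }
  idx <- seq_len(m)
  r <- rho^abs(outer(idx, idx, "-"))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%02d", idx)
  ld_matrix(r, snp_ids)
}

#' Repair a nearly-PSD correlation matrix
#'
#' Clips negative eigenvalues to a small floor and rescales to a unit
#' diagonal, so that downstream Cholesky factorization is guaranteed to
#' succeed on user-supplied matrices that fail positive semi-definiteness
#' by rounding.
#'
#' @param r Square symmetric matrix with SNP-id dimnames.
#' @param eig_floor Eigenvalue floor, default `1e-8`.
#' @return An [ld_matrix()].
#' @export
repair_ld <- function(r, eig_floor = 1e-8) {
  r <- as.matrix(r)
  snp_ids <- rownames(r)
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  ld_matrix(r, snp_ids)
}

#' Read / write an LD matrix as whitespace-delimited text
#'
#' The on-disk format is a header row of SNP identifiers followed by the
#' square numeric matrix, whitespace-delimited.
#'
#' @param path File path.
#' @return `read_ld_matrix`: an [ld_matrix()]. `write_ld_matrix`: the path,
#'   invisibly.
#' @export
read_ld_matrix <- function(path) {
  header <- strsplit(trimws(readLines(path, n = 1)), "[ \t]+")[[1]]
  r <- as.matrix(utils::read.table(path, skip = 1, header = FALSE))
  if (ncol(r) != length(header)) stop("LD matrix is not square: ", path)
  ld_matrix(unname(r), header)
}

#' @rdname read_ld_matrix
#' @param ld An [ld_matrix()] to write.
#' @export
write_ld_matrix <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(ld), collapse = "\t"), con)
  utils::write.table(.fmt_table(as.data.frame(unclass(ld))), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
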