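# Internal numerical helpers shared across modules.

# 32-bit unsigned product modulo 2^32, computed in doubles.
# Splitting the first factor keeps every intermediate below 2^49 < 2^53.
.mul32 <- function(a, b) {
  a <- a %% 4294967296
  b <- b %% 4294967296
  hi <- floor(a / 65536)
  lo <- a %% 65536
  (((hi * b) %% 4294967296) * 65536 + lo * b) %% 4294967296
}

# 32-bit XOR on doubles holding unsigned 32-bit values.
.xor32 <- function(a, b) {
  ah <- floor(a / 65536); al <- a %% 65536
  bh <- floor(b / 65536); bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

# splitmix-style 32-bit finalizer: a well-mixed deterministic hash of a
# non-negative integer state. Used to derive independent per-gene
# sub-streams from one global seed.
.splitmix32 <- function(x) {
  z <- (x + 2654435769) %% 4294967296
  z <- .xor32(z, floor(z / 65536))
  z <- .mul32(z, 2246822507)   # 0x85ebca6b
  z <- .xor32(z, floor(z / 8192))
  z <- .mul32(z, 3266489909)   # 0xc2b2ae35
  .xor32(z, floor(z / 65536))
}

#' Derive a reproducible sub-seed from a global seed and a stream index
#'
#' Per-gene (and per-stage) random streams are derived from one global
#' integer seed by a splitmix-style hash, so that simulating gene k does not
#' depend on how many genes were simulated before it.
#'
#' @param seed Global integer seed (non-negative).
#' @param index Non-negative integer stream index.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
sub_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0,
            is.numeric(index), length(index) == 1, index >= 0)
  as.integer(.splitmix32(.splitmix32(seed %% 4294967296) + index) %% 2147483647)
}

# log(sum(exp(x))) with the usual max shift; empty input -> -Inf.
.logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, clamped to -Inf when the difference
# vanishes within rounding. Guards the H3 term against cancellation.
.logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  d <- b - a
  res <- a + log1p(-exp(d))
  if (!is.finite(res)) -Inf else res
}

# FNV-1a 32-bit hash of a character string; used for config fingerprints.
.fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- .xor32(h, b %% 256)
    h <- .mul32(h, 16777619)
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

# Stable decimal formatting so that written tables are byte-identical
# across runs with identical inputs.
.fmt_num <- function(x, digits = 10) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

# Format every numeric column of a data.frame for deterministic output.
.fmt_table <- function(df, digits = 10) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- .fmt_num(df[[j]], digits)
    }
  }
  df
}

.write_tsv <- function(df, path, digits = 10) {
  utils::write.table(.fmt_table(df, digits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
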