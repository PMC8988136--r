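## small shared helpers, internal

`%||%` <- function(a, b) if (is.null(a)) b else a

## sign() that never returns 0 (ties treated as positive)
sign1 <- function(x) ifelse(x < 0, -1, 1)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b, guarded against cancellation
log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

## z-score implied by a two-sided p-value and an effect sign
z_from_p <- function(p, beta) sign1(beta) * qnorm(p / 2, lower.tail = FALSE)

## numeric chromosome order (X/Y/MT after autosomes)
chrom_rank <- function(chrom) {
  ch <- toupper(as.character(chrom))
  r <- suppressWarnings(as.numeric(ch))
  r[ch == "X"] <- 23
  r[ch == "Y"] <- 24
  r[ch %in% c("MT", "M")] <- 25
  r[is.na(r)] <- 26
  r
}

## derived per-stage seed streams from one master seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
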