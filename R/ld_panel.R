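## Block-LD reference panel: variant map, correlation matrix, LD scores.

#' Build a block-LD reference panel
#'
#' Constructs a synthetic LD reference with a block-diagonal correlation
#' matrix: within a block, `r[j,k] = rho^|j-k|` (first-order autoregressive
#' decay); zero across blocks. Each block carries one minor-allele frequency
#' drawn uniformly from `maf_range` (constant MAF within a block keeps the
#' haplotype simulator's realized LD exactly equal to this matrix; see
#' [simulate_pair_sumstats()]). Per-variant LD scores
#' `ell_j = sum_k r[j,k]^2` are precomputed. Blocks are laid out round-robin
#' over 22 chromosomes, 5 kb between adjacent variants within a block and
#' 1 Mb between block starts, so within-block pairs are always inside the
#' usual clumping distance windows and across-block pairs are LD-free.
#'
#' @param config a [sim_config()] (fields `M`, `block_size`, `rho`,
#'   `maf_range`, `seed` are used).
#' @return An `ld_panel`: list with `map` (variant_id, chrom, pos, alleles,
#'   maf, block), `r` (M x M correlation matrix), `ld_scores`, `M`,
#'   `block_size`, `rho`.
#' @export
make_ld_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$M; bs <- config$block_size; rho <- config$rho
  stop_if(any(rho < 0 | rho >= 1), "rho must be in [0, 1)")
  stop_if(bs < 1, "block size must be >= 1")
  set.seed(derive_seed(config$seed, 11L))

  n_blocks <- ceiling(M / bs)
  block <- rep(seq_len(n_blocks), each = bs)[seq_len(M)]
  rho_blk <- rep_len(rho, n_blocks)
  maf_blk <- runif(n_blocks, config$maf_range[1], config$maf_range[2])

  chrom <- as.character(((seq_len(n_blocks) - 1L) %% 22L) + 1L)[block]
  blk_on_chr <- stats::ave(seq_len(n_blocks), ((seq_len(n_blocks) - 1L) %% 22L),
                           FUN = seq_along)
  within <- stats::ave(seq_len(M), block, FUN = seq_along)
  pos <- blk_on_chr[block] * 1e6 + within * 5e3

  ## non-palindromic allele pairs only, so harmonization keeps everything
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(nrow(pairs), M, replace = TRUE)

  r <- matrix(0, M, M)
  ld <- numeric(M)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    rb <- rho_blk[b] ^ abs(outer(seq_along(idx), seq_along(idx), "-"))
    r[idx, idx] <- rb
    ld[idx] <- rowSums(rb ^ 2)
  }

  map <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(M)),
    chrom = chrom, pos = pos,
    effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
    maf = maf_blk[block], block = block, rho = rho_blk[block],
    stringsAsFactors = FALSE
  )
  structure(list(map = map, r = r, ld_scores = ld, M = M,
                 block_size = bs, rho = rho, rho_block = rho_blk),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("<ld_panel>", x$M, "variants,", max(x$map$block), "blocks | mean LD score",
      round(mean(x$ld_scores), 3), "\n")
  invisible(x)
}

#' Pairwise LD (r-squared) lookup
#'
#' @param panel an `ld_panel`.
#' @param ids_a,ids_b variant ids; returns the r-squared matrix between them.
#' @export
ld_r2 <- function(panel, ids_a, ids_b = ids_a) {
  i <- match(ids_a, panel$map$variant_id)
  j <- match(ids_b, panel$map$variant_id)
  stop_if(anyNA(i) || anyNA(j), "variant(s) not covered by the panel")
  panel$r[i, j, drop = FALSE] ^ 2
}

#' Write / read an LD panel as plain-text files
#'
#' The variant map goes to `<prefix>.map.tsv` and the dense correlation
#' matrix to `<prefix>.r.tsv` (desk-scale panels only).
#' @param panel an `ld_panel`.
#' @param prefix file path prefix.
#' @export
write_ld_panel <- function(panel, prefix) {
  data.table::fwrite(panel$map, paste0(prefix, ".map.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(panel$r), paste0(prefix, ".r.tsv"),
                     sep = "\t", col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_ld_panel
#' @export
read_ld_panel <- function(prefix) {
  map <- data.table::fread(paste0(prefix, ".map.tsv"), sep = "\t",
                           data.table = FALSE)
  map$chrom <- as.character(map$chrom)
  r <- as.matrix(data.table::fread(paste0(prefix, ".r.tsv"), sep = "\t",
                                   header = FALSE, data.table = FALSE))
  dimnames(r) <- NULL
  rho_blk <- rowsum(map$rho, map$block)[, 1] / tabulate(map$block)
  structure(list(map = map, r = r, ld_scores = rowSums(r ^ 2), M = nrow(map),
                 block_size = max(tabulate(map$block)),
                 rho = rho_blk, rho_block = rho_blk),
            class = "ld_panel")
}
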