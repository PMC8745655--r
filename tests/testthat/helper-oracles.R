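# Independent oracles used across the suite. Each one is deliberately a
# different route than the implementation it checks.

# quantile normalization: sort each column, average across columns by row,
# map back by within-column rank (tie-free inputs only)
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- ref[rank(m[, j])]
  out
}

# Benjamini-Hochberg by the literal step-up definition:
# p_adj(i) = min over k with p(k) >= p(i) of m * p(k) / rank(k)
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    ks <- which(p >= p[i] | r >= r[i])
    min(1, min(m * p[ks] / r[ks]))
  }, numeric(1))
}

# exhaustive evaluator of the two-tier rule on a long call table
two_tier_oracle <- function(calls, thr, line_drugs) {
  vapply(unique(calls$mirna), function(m) {
    df <- calls[calls$mirna == m, ]
    sig <- if (thr$strict_alpha) df$p_adj < thr$alpha else df$p_adj <= thr$alpha
    big <- if (thr$strict_fold) abs(df$fold) > thr$fold_cut else
      abs(df$fold) >= thr$fold_cut
    called <- sig & big
    tier1 <- FALSE
    for (d in unique(line_drugs)) {
      lines_d <- names(line_drugs)[line_drugs == d]
      idx <- df$cell_line %in% lines_d
      if (sum(idx) >= 2 && all(called[idx])) tier1 <- TRUE
    }
    tier2 <- any(abs(df$fold) >= thr$fold_cut_single & sig)
    tier1 || tier2
  }, logical(1))
}

# brute-force inverse-pair filter over every edge x cell line combination
inverse_pairs_oracle <- function(mir_de, gene_de, db, thr) {
  hits <- list()
  for (i in seq_len(nrow(db))) {
    for (ln in unique(mir_de$cell_line)) {
      mr <- mir_de[mir_de$mirna == db$mirna[i] & mir_de$cell_line == ln, ]
      gr <- gene_de[gene_de$gene == db$gene[i] & gene_de$cell_line == ln, ]
      if (nrow(mr) != 1 || nrow(gr) != 1) next
      pass <- function(f, p) abs(f) > thr$fold_cut && p < thr$alpha
      if (pass(mr$fold, mr$p_adj) && pass(gr$fold, gr$p_adj) &&
          sign(mr$fold) * sign(gr$fold) == -1)
        hits[[length(hits) + 1]] <-
          data.frame(mirna = db$mirna[i], gene = db$gene[i], cell_line = ln)
    }
  }
  if (!length(hits)) return(data.frame(mirna = character(),
                                       gene = character(),
                                       cell_line = character()))
  out <- do.call(rbind, hits)
  out[order(out$cell_line, out$mirna, out$gene), ]
}

# random long call table for property tests
random_call_table <- function(n_mirna, seed) {
  set.seed(seed)
  lines <- names(default_line_drugs())
  expand <- expand.grid(mirna = sprintf("m%02d", seq_len(n_mirna)),
                        cell_line = lines, stringsAsFactors = FALSE)
  expand$fold <- signed_fold(stats::runif(nrow(expand), -4.5, 4.5))
  expand$p_adj <- stats::runif(nrow(expand))^2
  expand
}

pair_key <- function(d) sort(paste(d$mirna, d$gene, d$cell_line, sep = "|"))
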