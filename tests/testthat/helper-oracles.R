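# independent oracles (never call package internals beyond public surface)

# full-enumeration Mann-Whitney oracle: two-tailed exact p for tie-free x, y
mwu_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  # ranks of the pooled sample are fixed; enumerate U over all assignments
  combs <- utils::combn(nx + ny, nx)
  u_null <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# construct a tie-free sample pair with a prescribed U statistic:
# choose the x-ranks as a subset of 1..n with rank-sum U + nx(nx+1)/2
sample_with_u <- function(nx, ny, u) {
  n <- nx + ny
  target <- u + nx * (nx + 1) / 2
  ranks <- seq_len(nx)  # minimal rank-sum
  excess <- target - sum(ranks)
  for (i in rev(seq_len(nx))) {
    room <- (n - (nx - i)) - ranks[i]
    add <- min(room, excess)
    ranks[i] <- ranks[i] + add
    excess <- excess - add
    if (excess == 0) break
  }
  stopifnot(excess == 0)
  x <- as.numeric(ranks)
  y <- as.numeric(setdiff(seq_len(n), ranks))
  list(x = x, y = y)
}

# brute-force RSCU oracle over a character vector of CDS strings
rscu_oracle <- function(seqs) {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  sense <- names(code)[code != "*"]
  counts <- stats::setNames(numeric(length(sense)), sense)
  for (s in seqs) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (cods[length(cods)] %in% stops) cods <- cods[-length(cods)]
    for (cd in cods) counts[cd] <- counts[cd] + 1
  }
  vals <- stats::setNames(rep(NA_real_, length(sense)), sense)
  for (a in unique(code[sense])) {
    fam <- sense[code[sense] == a]
    tot <- sum(counts[fam])
    if (tot > 0) vals[fam] <- counts[fam] / (tot / length(fam))
  }
  list(counts = counts, rscu = vals)
}

# random in-frame CDS with no internal stop, ATG start, TAA end
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}
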