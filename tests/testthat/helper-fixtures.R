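# shared fixtures and independent oracles

# quick harmonized set without allele bookkeeping
make_h <- function(gamma, Gamma, se_y, se_x = rep(0.01, length(gamma)),
                   ids = paste0("rs", seq_along(gamma))) {
  harmonized_set(ids, gamma, se_x, Gamma, se_y)
}

# 3-SNP fixture used for the IVW oracle checks
h3 <- function() {
  make_h(gamma = c(0.3, 0.5, 0.8),
         Gamma = c(0.07, 0.09, 0.18),
         se_y = c(0.02, 0.03, 0.025))
}

# 4-SNP fixture used for the Egger oracle checks (spread in gamma)
h4 <- function() {
  make_h(gamma = c(0.2, 0.35, 0.55, 0.9),
         Gamma = c(0.08, 0.12, 0.15, 0.3),
         se_y = c(0.02, 0.025, 0.03, 0.02))
}

# independent WLS oracles via stats::lm (generic regression route, distinct
# from the closed-form sums inside the package)
oracle_ivw_slope <- function(h) {
  unname(coef(lm(Gamma ~ 0 + gamma, data = as.data.frame(h),
                 weights = 1 / h$se_y^2)))
}
oracle_egger <- function(h) {
  flip <- h$gamma < 0
  d <- data.frame(g = ifelse(flip, -h$gamma, h$gamma),
                  G = ifelse(flip, -h$Gamma, h$Gamma))
  unname(coef(lm(G ~ g, data = d, weights = 1 / h$se_y^2)))
}

# summary_stats straight from vectors
make_stats <- function(ids, pval, beta = 0.1, se = 0.01, eaf = 0.3,
                       chrom = "1", pos = seq_along(ids) * 2e7,
                       ea = "A", oa = "G", trait = "trait",
                       type = "continuous", n = 1e5) {
  k <- length(ids)
  summary_stats(data.frame(variant_id = ids, chrom = rep_len(chrom, k),
                           pos = rep_len(pos, k),
                           effect_allele = rep_len(ea, k),
                           other_allele = rep_len(oa, k),
                           eaf = rep_len(eaf, k), beta = rep_len(beta, k),
                           se = rep_len(se, k), pval = rep_len(pval, k),
                           n = rep_len(n, k), stringsAsFactors = FALSE),
                trait, type)
}

# harmonization-free path from a simulated pair (same allele layout on both
# sides by construction)
pair_to_h <- function(pair) {
  harmonized_set(pair$exposure$variant_id,
                 pair$exposure$beta, pair$exposure$se,
                 pair$outcome$beta, pair$outcome$se)
}
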