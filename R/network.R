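#' Bidirectional MR network among significant traits
#'
#' For every ordered pair of traits, runs the MR pipeline with one trait as
#' exposure and the other as outcome and adds a directed edge when the
#' headline p-value is below `alpha` (nominal 0.05 — intermediate-factor
#' screening applies no multiplicity correction). Each trait must supply
#' both an instrument panel (its own GWAS restricted to, or at least
#' containing, its instruments) and a full association panel in which other
#' traits' instruments can be looked up. Optionally appends edges from each
#' trait to the disease outcome taken from an existing atlas result.
#'
#' @param traits Named list; each element is a list with `instruments`
#'   (a [summary_stats()] exposure panel) and `panel` (a [summary_stats()]
#'   outcome-side panel for that trait).
#' @param alpha Edge threshold on the headline p-value (default 0.05).
#' @param p_instrument Instrument-selection threshold (default 5e-8).
#' @param seed Master seed for the stochastic estimator components.
#' @param n_boot Weighted-median bootstrap draws.
#' @param egger_substitution Passed through to the headline rule.
#' @param atlas_results Optional [run_atlas()] result supplying
#'   trait-to-disease edges.
#' @param outcome_name Disease node label used when `atlas_results` is
#'   given.
#' @return A `causal_network`: list with `nodes` and `edges` (data frame
#'   `source target beta se pval sign method`). Pairs with no usable
#'   instruments are skipped and listed in attribute `"skipped"`.
#' @export
build_network <- function(traits, alpha = 0.05, p_instrument = 5e-8,
                          seed = 1L, n_boot = 1000L, egger_substitution = TRUE,
                          atlas_results = NULL, outcome_name = "outcome") {
  stopifnot(is.list(traits), !is.null(names(traits)))
  nms <- names(traits)
  edges <- list()
  skipped <- character(0)
  for (a in nms) {
    for (b in nms) {
      if (a == b) next  # no self-edges
      res <- tryCatch({
        instruments <- select_instruments(traits[[a]]$instruments, p_instrument)
        h <- harmonize(instruments, traits[[b]]$panel)
        est <- mr_all(h, n_boot = n_boot,
                      seed = derive_seed(seed, paste0(a, ">", b)))
        .headline(est, egger_substitution)
      }, mratlas_error = function(e) NULL)
      if (is.null(res)) {
        skipped <- c(skipped, paste0(a, " -> ", b))
        next
      }
      e <- res$estimate
      if (e$pval < alpha) {
        edges[[paste0(a, ">", b)]] <-
          data.frame(source = a, target = b, beta = e$beta, se = e$se,
                     pval = e$pval, sign = ifelse(e$beta >= 0, "+", "-"),
                     method = res$method, stringsAsFactors = FALSE)
      }
    }
  }
  nodes <- nms
  if (!is.null(atlas_results)) {
    nodes <- c(nodes, outcome_name)
    for (r in atlas_results) {
      if (r$status == "ok" && r$exposure %in% nms && r$headline$pval < alpha) {
        e <- r$headline
        edges[[paste0(r$exposure, ">", outcome_name)]] <-
          data.frame(source = r$exposure, target = outcome_name, beta = e$beta,
                     se = e$se, pval = e$pval,
                     sign = ifelse(e$beta >= 0, "+", "-"),
                     method = r$headline_method, stringsAsFactors = FALSE)
      }
    }
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0), beta = numeric(0),
               se = numeric(0), pval = numeric(0), sign = character(0),
               method = character(0), stringsAsFactors = FALSE)
  rownames(edge_df) <- NULL
  structure(list(nodes = nodes, edges = edge_df),
            class = "causal_network", skipped = skipped)
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %d node(s), %d directed edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -%s-> %s (|beta| %.3f, p %.3g)\n",
                  x$edges$source[i], x$edges$sign[i], x$edges$target[i],
                  abs(x$edges$beta[i]), x$edges$pval[i]))
    }
  }
  invisible(x)
}

#' Write a network edge list as TSV
#'
#' Columns `source target beta se pval sign method`; one row per directed
#' edge.
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "causal_network"))
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}
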