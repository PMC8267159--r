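#' Linkage-disequilibrium matrix
#'
#' Squared-correlation (r^2) matrix over a set of variants, with the base-pair
#' coordinates needed to apply a physical clumping window. Stands in for the
#' external reference panel a production pipeline would query.
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param r2 Square symmetric matrix of squared correlations in \[0,1\] with
#'   unit diagonal, ordered as `variant_ids`.
#' @param positions Base-pair positions (1-based) aligned to `variant_ids`.
#' @param chrom Chromosome labels aligned to `variant_ids` (recycled if
#'   length 1).
#' @return An `ld_matrix` object (list with elements `variant_ids`, `r2`,
#'   `positions`, `chrom`).
#' @export
ld_matrix <- function(variant_ids, r2, positions, chrom = "1") {
  r2 <- as.matrix(r2)
  n <- length(variant_ids)
  stopifnot(nrow(r2) == n, ncol(r2) == n, length(positions) == n)
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0,1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2,
                 positions = as.numeric(positions),
                 chrom = rep_len(as.character(chrom), n)),
            class = "ld_matrix")
}

#' Read an LD matrix from a long-format triple file
#'
#' Accepts a tab-separated file with columns `id_a id_b r2`; pairs absent
#' from the file are taken as r^2 = 0. Positions must be supplied separately
#' (they are a property of the variants, not of the pairs).
#'
#' @param path Path to the triple file.
#' @param positions Named numeric vector of base-pair positions covering at
#'   least the variants named in the file.
#' @param chrom Named character vector of chromosomes (or a single label).
#' @return An [ld_matrix()] object.
#' @export
read_ld_triples <- function(path, positions, chrom = "1") {
  tri <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"))
  stopifnot(all(c("id_a", "id_b", "r2") %in% names(tri)))
  ids <- sort(unique(c(tri$id_a, tri$id_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  for (k in seq_len(nrow(tri))) {
    m[tri$id_a[k], tri$id_b[k]] <- tri$r2[k]
    m[tri$id_b[k], tri$id_a[k]] <- tri$r2[k]
  }
  if (is.null(names(positions))) stop("`positions` must be named", call. = FALSE)
  ch <- if (length(chrom) == 1L) rep(chrom, length(ids)) else chrom[ids]
  ld_matrix(ids, m, positions[ids], ch)
}

#' Greedy LD clumping of summary statistics
#'
#' Prunes a set of variant associations to an approximately independent
#' subset: repeatedly keep the remaining variant with the smallest p-value
#' and discard every remaining same-chromosome variant within `window_kb`
#' (center-to-center) whose squared correlation with it exceeds `r2_max`.
#' Defaults (r^2 = 0.001 within 10,000 kb) give the near-independence
#' commonly required for inverse-variance weighting of per-variant ratios.
#'
#' Variants absent from `ld` are treated as independent of everything, with
#' one warning listing them (the reference panel behind a user's LD matrix
#' rarely covers every scored variant). Equal p-values are broken
#' lexicographically by `variant_id` so results are deterministic.
#'
#' @param stats A [summary_stats()] object.
#' @param ld An [ld_matrix()] or `NULL` (all variants treated as independent;
#'   the physical-window rule still requires r^2 evidence, so nothing is
#'   discarded).
#' @param r2_max Maximum allowed squared correlation between retained
#'   variants; default 0.001.
#' @param window_kb Physical window in kilobases; default 10,000.
#' @return A [summary_stats()] object with the retained variants ordered by
#'   ascending p-value.
#' @export
ld_clump <- function(stats, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"))
  stopifnot(is.numeric(r2_max), r2_max >= 0, r2_max < 1,
            is.numeric(window_kb), window_kb > 0)
  df <- as.data.frame(stats)
  if (nrow(df) <= 1L) return(.restat(stats, df))

  if (is.null(ld)) {
    known <- character(0)
  } else {
    stopifnot(inherits(ld, "ld_matrix"))
    known <- ld$variant_ids
  }
  missing <- setdiff(df$variant_id, known)
  if (length(missing) && !is.null(ld)) {
    warning(sprintf("%d variant(s) absent from LD matrix treated as independent: %s",
                    length(missing),
                    paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  }

  ord <- order(df$pval, df$variant_id)
  df <- df[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(df))
  kept <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (!length(cand)) break
    same_chr <- df$chrom[cand] == df$chrom[i]
    in_window <- abs(df$pos[cand] - df$pos[i]) <= window_kb * 1000
    r2_with <- rep(0, length(cand))
    if (df$variant_id[i] %in% known) {
      hit <- df$variant_id[cand] %in% known
      r2_with[hit] <- ld$r2[df$variant_id[i], df$variant_id[cand][hit]]
    }
    drop <- same_chr & in_window & r2_with > r2_max
    alive[cand[drop]] <- FALSE
  }
  out <- df[kept, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("clumping trait '%s': %d in, %d retained",
                  trait_name(stats), nrow(df), nrow(out)))
  .restat(stats, out)
}
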