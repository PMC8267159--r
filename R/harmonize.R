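#' Harmonized instrument set
#'
#' The unit every causal estimator consumes: J instruments with
#' exposure effects (`gamma`, SE `se_x`) and outcome effects (`Gamma`, SE
#' `se_y`) expressed for a common effect allele. Usually produced by
#' [harmonize()]; the constructor is exported so simulations and tests can
#' build sets directly.
#'
#' @param variant_id Character vector of instrument identifiers.
#' @param gamma,se_x Variant-exposure effects and standard errors.
#' @param Gamma,se_y Variant-outcome effects and standard errors.
#' @param effect_allele,other_allele Aligned allele labels (optional).
#' @param eaf Effect-allele frequency in the exposure panel (optional).
#' @param palindromic,flipped Logical flags recording harmonization actions.
#' @param exposure,outcome Trait names carried as attributes.
#' @param dropped Data frame (`variant_id`, `reason`) of variants removed
#'   during harmonization.
#' @return A `harmonized_set` (data frame subclass).
#' @export
harmonized_set <- function(variant_id, gamma, se_x, Gamma, se_y,
                           effect_allele = NA_character_,
                           other_allele = NA_character_,
                           eaf = NA_real_,
                           palindromic = FALSE, flipped = FALSE,
                           exposure = "exposure", outcome = "outcome",
                           dropped = NULL) {
  J <- length(variant_id)
  if (J < 1L) .mratlas_error("mratlas_no_instruments", "empty instrument set")
  stopifnot(length(gamma) == J, length(Gamma) == J,
            length(se_x) == J, length(se_y) == J)
  if (any(se_x <= 0) || any(se_y <= 0)) {
    stop("all standard errors must be > 0", call. = FALSE)
  }
  df <- data.frame(variant_id = as.character(variant_id),
                   effect_allele = rep_len(effect_allele, J),
                   other_allele = rep_len(other_allele, J),
                   gamma = as.numeric(gamma), se_x = as.numeric(se_x),
                   Gamma = as.numeric(Gamma), se_y = as.numeric(se_y),
                   eaf = rep_len(as.numeric(eaf), J),
                   palindromic = rep_len(palindromic, J),
                   flipped = rep_len(flipped, J),
                   stringsAsFactors = FALSE)
  if (is.null(dropped)) {
    dropped <- data.frame(variant_id = character(0), reason = character(0))
  }
  structure(df, class = c("harmonized_set", "data.frame"),
            exposure = exposure, outcome = outcome, dropped = dropped)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d instrument(s), %d dropped\n",
              attr(x, "exposure"), attr(x, "outcome"), nrow(x),
              nrow(attr(x, "dropped"))))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param h A [harmonized_set()].
#' @export
n_instruments <- function(h) nrow(h)

.complement <- c(A = "T", T = "A", C = "G", G = "C")
.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Align exposure and outcome summary statistics to a common effect allele
#'
#' For every variant shared between the two panels the outcome effect is
#' re-expressed for the exposure's effect allele: identical allele pairs pass
#' through; swapped pairs have the outcome beta sign-flipped and EAF
#' complemented; pairs that only match after strand complementation are
#' complemented first. Palindromic variants (A/T, C/G), whose strand cannot
#' be read off the alleles, are resolved by allele-frequency concordance:
#' retained when both EAFs lie outside the ambiguity band (flipping if the
#' frequencies disagree about which allele is the minor one), dropped when
#' either EAF falls inside the band or is missing. Irreconcilable allele
#' pairs are dropped with a reason.
#'
#' @param exposure,outcome [summary_stats()] objects sharing at least one
#'   `variant_id`.
#' @param eaf_band Ambiguity band for palindromic resolution; default
#'   `c(0.42, 0.58)`.
#' @return A [harmonized_set()]; dropped variants and reasons are in
#'   `attr(, "dropped")`.
#' @export
harmonize <- function(exposure, outcome, eaf_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (!length(shared)) {
    .mratlas_error("mratlas_no_instruments",
                   "no shared variants between exposure and outcome panels")
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$variant_id), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$variant_id), ]

  n <- length(shared)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flipped <- rep(FALSE, n)
  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)
  Gamma <- ou$beta
  eaf_y <- ou$eaf

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (pal[i]) {
      # strand is unreadable from alleles; the allele pair always "matches"
      if (!((ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x))) {
        keep[i] <- FALSE; reason[i] <- "allele pair irreconcilable"; next
      }
      fx <- ex$eaf[i]
      fy <- if (ea_y == ea_x) ou$eaf[i] else 1 - ou$eaf[i]
      if (ea_y != ea_x) Gamma[i] <- -Gamma[i]  # provisional swap alignment
      if (is.na(fx) || is.na(fy) ||
          (fx >= eaf_band[1] && fx <= eaf_band[2]) ||
          (fy >= eaf_band[1] && fy <= eaf_band[2])) {
        keep[i] <- FALSE; reason[i] <- "palindromic, ambiguous EAF"; next
      }
      if ((fx < 0.5) != (fy < 0.5)) {
        # frequencies discordant: the outcome panel reports the other strand
        Gamma[i] <- -Gamma[i]
        fy <- 1 - fy
        flipped[i] <- TRUE
      }
      eaf_y[i] <- fy
    } else {
      cy_e <- .complement[ea_y]; cy_o <- .complement[oa_y]
      if (ea_y == ea_x && oa_y == oa_x) {
        # aligned as-is
      } else if (ea_y == oa_x && oa_y == ea_x) {
        Gamma[i] <- -Gamma[i]; eaf_y[i] <- 1 - eaf_y[i]; flipped[i] <- TRUE
      } else if (cy_e == ea_x && cy_o == oa_x) {
        # other strand, same orientation
      } else if (cy_e == oa_x && cy_o == ea_x) {
        Gamma[i] <- -Gamma[i]; eaf_y[i] <- 1 - eaf_y[i]; flipped[i] <- TRUE
      } else {
        keep[i] <- FALSE; reason[i] <- "allele pair irreconcilable"
      }
    }
  }

  dropped <- data.frame(variant_id = shared[!keep], reason = reason[!keep])
  if (!any(keep)) {
    .mratlas_error("mratlas_no_instruments",
                   "all shared variants dropped during harmonization")
  }
  harmonized_set(variant_id = shared[keep],
                 gamma = ex$beta[keep], se_x = ex$se[keep],
                 Gamma = Gamma[keep], se_y = ou$se[keep],
                 effect_allele = ex$effect_allele[keep],
                 other_allele = ex$other_allele[keep],
                 eaf = ex$eaf[keep],
                 palindromic = pal[keep], flipped = flipped[keep],
                 exposure = trait_name(exposure), outcome = trait_name(outcome),
                 dropped = dropped)
}
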