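#' GWAS summary statistics for one trait
#'
#' A `summary_stats` object is a validated data frame of per-variant
#' association records for a single trait, the unit the instrument-selection,
#' clumping and harmonization steps operate on. Columns are
#' `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`; trait metadata (name, type, case/control counts
#' for binary traits) travels as attributes.
#'
#' Effect sizes are taken on the source scale: per standard deviation for
#' continuous traits, log-odds for binary traits. No rescaling is applied.
#'
#' @param records Data frame with the columns listed above (`eaf` and `n`
#'   may be `NA`).
#' @param trait_name Character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_cases,n_controls Case/control counts for binary traits.
#' @return A `summary_stats` object. Rows failing the per-record invariants
#'   (positive SE, p-value in (0,1], alleles in A/C/G/T and distinct, EAF in
#'   \[0,1\] when present) are rejected; the rejected rows and their reasons
#'   are attached as attribute `"rejected"` and a message reports the counts.
#' @export
summary_stats <- function(records, trait_name, trait_type = c("continuous", "binary"),
                          n_cases = NA_integer_, n_controls = NA_integer_) {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    .mratlas_error("mratlas_format_error",
                   paste0("missing required column(s): ",
                          paste(missing_cols, collapse = ", ")))
  }
  records <- as.data.frame(records)[required]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  dup <- unique(records$variant_id[duplicated(records$variant_id)])
  if (length(dup)) {
    .mratlas_error("mratlas_duplicate_error",
                   paste0("duplicate variant_id in trait '", trait_name, "': ",
                          paste(head(dup, 5L), collapse = ", ")))
  }

  reason <- rep(NA_character_, nrow(records))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(records$beta), "non-numeric or missing beta")
  reason <- bad(is.na(records$se), "non-numeric or missing se")
  reason <- bad(!is.na(records$se) & records$se <= 0, "se not > 0")
  reason <- bad(is.na(records$pval) | records$pval <= 0 | records$pval > 1,
                "pval not in (0,1]")
  reason <- bad(!records$effect_allele %in% c("A", "C", "G", "T"),
                "effect_allele not in {A,C,G,T}")
  reason <- bad(!records$other_allele %in% c("A", "C", "G", "T"),
                "other_allele not in {A,C,G,T}")
  reason <- bad(records$effect_allele == records$other_allele,
                "effect_allele equals other_allele")
  reason <- bad(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1),
                "eaf outside [0,1]")

  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(rejected)) {
    message(sprintf("trait '%s': read %d, rejected %d, retained %d record(s)",
                    trait_name, nrow(records), nrow(rejected), nrow(kept)))
  }

  structure(kept,
            class = c("summary_stats", "data.frame"),
            trait_name = trait_name,
            trait_type = trait_type,
            n_cases = as.integer(n_cases),
            n_controls = as.integer(n_controls),
            rejected = rejected)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s): %d variant(s)\n",
              trait_name(x), attr(x, "trait_type"), nrow(x)))
  if (!is.na(attr(x, "n_cases"))) {
    cat(sprintf("  cases/controls: %d/%d\n",
                attr(x, "n_cases"), attr(x, "n_controls")))
  }
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 5L))
  invisible(x)
}

#' @rdname summary_stats
#' @param x A `summary_stats` object.
#' @export
trait_name <- function(x) attr(x, "trait_name")

# keep class + metadata when subsetting rows
.restat <- function(template, rows) {
  structure(rows,
            class = c("summary_stats", "data.frame"),
            trait_name = attr(template, "trait_name"),
            trait_type = attr(template, "trait_type"),
            n_cases = attr(template, "n_cases"),
            n_controls = attr(template, "n_controls"),
            rejected = attr(template, "rejected"))
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Expects a header row with columns `variant_id chrom pos effect_allele
#' other_allele eaf beta se pval n` (`eaf` and `n` may be `NA`). Rows failing
#' validation are rejected with a per-row reason (see [summary_stats()]).
#'
#' @param path Path to the TSV file.
#' @inheritParams summary_stats
#' @return A [summary_stats()] object.
#' @export
read_summary_tsv <- function(path, trait_name, trait_type = c("continuous", "binary"),
                             n_cases = NA_integer_, n_controls = NA_integer_) {
  if (!file.exists(path)) {
    .mratlas_error("mratlas_format_error", paste0("file not found: ", path))
  }
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = c("NA", ""))
  summary_stats(raw, trait_name = trait_name, trait_type = trait_type,
                n_cases = n_cases, n_controls = n_controls)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Inverse of [read_summary_tsv()]: UTF-8, Unix newlines, `NA` for missing
#' `eaf`/`n`.
#'
#' @param stats A [summary_stats()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Select genome-wide significant instruments
#'
#' Retains variants associated with the trait at `pval < p_threshold`. The
#' default threshold is the conventional genome-wide significance level
#' 5e-8 used to enforce the relevance assumption of Mendelian randomization.
#'
#' @param stats A [summary_stats()] object.
#' @param p_threshold Significance threshold in (0,1); default `5e-8`.
#' @return A [summary_stats()] object with the retained records.
#'   If no record passes, an error of class `"mratlas_no_instruments"` is
#'   raised rather than returning a silently empty set.
#' @export
select_instruments <- function(stats, p_threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"))
  .assert_prob(p_threshold, "p_threshold", open_left = TRUE, open_right = FALSE)
  keep <- stats$pval < p_threshold
  if (!any(keep)) {
    .mratlas_error("mratlas_no_instruments",
                   sprintf("no instruments for trait '%s' at p < %g",
                           trait_name(stats), p_threshold))
  }
  out <- as.data.frame(stats)[keep, , drop = FALSE]
  rownames(out) <- NULL
  .restat(stats, out)
}
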