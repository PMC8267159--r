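#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Panel-level analyses need trait-level random streams that are independent
#' of analysis order but fully determined by one master seed. The sub-seed is
#' a 31-bit polynomial rolling hash of the label folded into the master seed,
#' so the same `(seed, label)` pair always yields the same stream and
#' different labels yield (for practical purposes) unrelated streams.
#'
#' @param seed Integer master seed.
#' @param label Character scalar, e.g. an `"exposure|outcome"` pair name.
#' @return A positive integer seed strictly below 2^31.
#' @export
#' @examples
#' derive_seed(42, "zinc|lung_cancer")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h) + 1L
}

# shared argument checks ------------------------------------------------------

.assert_prob <- function(x, name, open_left = TRUE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must be a probability in %s0,1%s, got %s",
                 name, if (open_left) "(" else "[",
                 if (open_right) ")" else "]",
                 format(x)), call. = FALSE)
  }
  invisible(x)
}

.mratlas_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "mratlas_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
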