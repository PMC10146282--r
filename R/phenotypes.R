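#' Simulate additive QTL phenotypes from gamete doses
#'
#' Phenotype = intercept + sum over QTL of beta * dose + Normal(0, sd) noise.
#' Supports several traits, each with its own QTL set.
#'
#' @param doses a `dose_matrix` (typically gamete doses).
#' @param qtl data.frame with columns `trait`, `window`, `beta`. Window ids
#'   must exist in `doses`.
#' @param intercept numeric intercept (recycled per trait).
#' @param sd residual standard deviation (recycled per trait).
#' @param seed optional integer seed.
#' @return data.frame with `id` and one column per trait.
#' @export
simulate_phenotypes <- function(doses, qtl, intercept = 0, sd = 1,
                                seed = NULL) {
  stopifnot(inherits(doses, "dose_matrix"),
            all(c("trait", "window", "beta") %in% names(qtl)))
  bad <- setdiff(qtl$window, colnames(doses$dose))
  if (length(bad)) stop("unknown QTL window id: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  traits <- unique(qtl$trait)
  intercept <- rep_len(intercept, length(traits))
  sd <- rep_len(sd, length(traits))
  out <- data.frame(id = rownames(doses$dose), stringsAsFactors = FALSE)
  for (i in seq_along(traits)) {
    q <- qtl[qtl$trait == traits[i], , drop = FALSE]
    x <- doses$dose[, q$window, drop = FALSE]
    x[is.na(x)] <- 1  # population mean dose of a duplex locus
    out[[traits[i]]] <- intercept[i] + as.vector(x %*% q$beta) +
      stats::rnorm(nrow(x), 0, sd[i])
  }
  out
}
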