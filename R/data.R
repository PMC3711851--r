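#' Curated worked-example values shipped with the package
#'
#' Two small reference tables of published summary values from a mouse
#' heat-shock study contrasting spermatocytes (SC, heat shock at 38/43
#' degrees C) and hepatocytes (HEP, 43 degrees C):
#'
#' * `worked_slr_examples()` -- per-gene mean log2 expression in control and
#'   heat-shocked cells together with the published signal log ratio, for
#'   cells whose printed means and SLR are arithmetically self-consistent at
#'   two decimals. Used to exercise the SLR arithmetic.
#' * `binding_crosstab_counts()` -- per-contrast counts of induced, repressed
#'   and HSF1-bound genes with their overlaps and the published percentage
#'   cells. Used to exercise the crosstab percentage arithmetic.
#'
#' @return A data frame.
#' @name worked_examples
NULL

#' @rdname worked_examples
#' @export
worked_slr_examples <- function() {
  utils::read.delim(system.file("extdata", "worked_slr_examples.tsv",
                                package = "heatshockr"),
                    stringsAsFactors = FALSE)
}

#' @rdname worked_examples
#' @export
binding_crosstab_counts <- function() {
  utils::read.delim(system.file("extdata", "binding_crosstab_counts.tsv",
                                package = "heatshockr"),
                    stringsAsFactors = FALSE)
}
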