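#' Cohort-level driver-discovery accounting
#'
#' Two bookkeeping identities used to summarize how much of a
#' mutation-negative cohort the combined exome + genome analysis explains.
#' `explained_driver_fraction()` is the share of previously mutation-negative
#' tumours with a candidate driver identified: exome-level analysis leaves
#' `unexplained_wes / mutation_negative` unexplained, and genome sequencing
#' of a subset resolves all but `unresolved_wgs / wgs_tested` of those, so
#' the explained share is
#' `1 - (unexplained_wes / mutation_negative) * (unresolved_wgs / wgs_tested)`.
#' `hh_ligand_fraction()` is the share attributable to structural variants
#' near hedgehog ligand genes: those found directly by exome analysis plus
#' the genome-level rate extrapolated to the exome-unexplained remainder.
#'
#' @param unexplained_wes Mutation-negative samples left unexplained after
#'   exome-level SCNA analysis.
#' @param mutation_negative Size of the mutation-negative cohort.
#' @param unresolved_wgs Genome-sequenced samples still unresolved.
#' @param wgs_tested Genome-sequenced sample count.
#' @return Fraction in `[0, 1]`.
#' @export
explained_driver_fraction <- function(unexplained_wes, mutation_negative,
                                      unresolved_wgs, wgs_tested) {
  1 - (unexplained_wes / mutation_negative) * (unresolved_wgs / wgs_tested)
}

#' @rdname explained_driver_fraction
#' @param sv_explained_wes Samples explained by hedgehog-ligand structural
#'   variants at the exome level.
#' @param hh_wgs Genome-sequenced samples whose driver is a hedgehog-ligand
#'   structural variant.
#' @export
hh_ligand_fraction <- function(sv_explained_wes, mutation_negative,
                               unexplained_wes, hh_wgs, wgs_tested) {
  sv_explained_wes / mutation_negative +
    (unexplained_wes / mutation_negative) * (hh_wgs / wgs_tested)
}

#' @export
autoplot.scna_calls <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df) +
    geom_segment(aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                     y = .data$logCR, yend = .data$logCR,
                     colour = .data$final_call),
                 linewidth = 1.5) +
    geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = "logCR", colour = "final call") +
    theme_minimal()
}

#' @export
tidy.scna_calls <- function(x, ...) as_tibble(x)
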