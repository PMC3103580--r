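#' Distribution of CP origins across families
#'
#' Stacked per-family bar chart of CP evolutionary origin labels: for every
#' family, how many of the CPs hitting it fall in each origin set (all three
#' kingdoms, the Archaea+Eukarya node, single kingdoms, ...).
#'
#' @param hits Hit tibble from [locate_hits()].
#' @param records Sequence record tibble.
#' @param drop_origins Origin labels to hide (e.g. `"B_only"` to expose the
#'   finer structure when one lineage dominates).
#' @return A ggplot object.
#' @export
plot_kingdom_origins <- function(hits, records, drop_origins = character(0)) {
  prof <- cp_kingdom_profiles(hits, records)
  fam_cp <- hits %>%
    inner_join(select(records, "id", "family"), by = c(seq_id = "id")) %>%
    distinct(.data$motif, .data$family) %>%
    inner_join(select(prof, "motif", "origin"), by = "motif") %>%
    filter(!.data$origin %in% drop_origins) %>%
    count(.data$family, .data$origin)
  ggplot2::ggplot(fam_cp, ggplot2::aes(.data$family, .data$n,
                                       fill = .data$origin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "CPs", fill = "Origin",
                  title = "CP origins per family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Enrichment overview plot
#'
#' Tile plot of the mitochondrial enrichment grid: families by kingdoms,
#' shaded by -log10 q, with enriched cells outlined.
#'
#' @param enrichment Result tibble of [mito_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  df <- enrichment %>% filter(!.data$skipped) %>%
    mutate(neglog_q = -log10(pmax(.data$q, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$kingdom, .data$family,
                                   fill = .data$neglog_q)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = filter(df, .data$enriched), fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(-log[10] * " q"),
                  title = "Kingdom-specific CP enrichment of mitochondrial sequences") +
    ggplot2::theme_minimal()
}
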