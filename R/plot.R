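# ggplot2 views of the main result types.

#' @export
autoplot.similarity_profile <- function(object, ...) {
  df <- object |>
    mutate(
      category = factor(.data$category, levels = .data$category),
      similarity = ifelse(.data$missing, 0, .data$similarity),
      status = ifelse(.data$missing, "missing", "hit")
    )
  ggplot(df, aes(x = .data$category, y = .data$similarity, fill = .data$status)) +
    geom_col() +
    scale_fill_manual(values = c(hit = "grey25", missing = "grey85"), name = NULL) +
    labs(
      x = "taxonomic category (nearest to farthest)",
      y = expression(-log[10] ~ "E-value"),
      title = attr(object, "query_id") %||% NULL
    ) +
    theme_minimal()
}

#' @export
autoplot.contamination_report <- function(object, ...) {
  df <- object$per_species |> filter(.data$n_reads > 0)
  ggplot(df, aes(x = .data$species, y = .data$n_reads)) +
    geom_col(fill = "grey25") +
    labs(x = "marker species", y = "reads attracted") +
    theme_minimal()
}

#' Bar plot of cluster sharing orders
#'
#' @param clusters An `ortho_clusters` tibble.
#' @param selected_species Species whose sharing order is counted.
#' @return A ggplot object.
#' @export
plot_sharing_orders <- function(clusters, selected_species) {
  order_k <- map_int(clusters$species, function(sp) {
    length(intersect(sp, selected_species))
  })
  df <- tibble(order = factor(order_k, levels = sort(unique(order_k)))) |>
    count(.data$order)
  ggplot(df, aes(x = .data$order, y = .data$n)) +
    geom_col(fill = "grey25") +
    labs(x = "species per cluster (sharing order)", y = "clusters") +
    theme_minimal()
}
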