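PLOT_KINDS <- c("spectrum", "profile96", "profile192", "compare",
                "contribution_bar", "contribution_heatmap", "cosine_heatmap",
                "strand_bias", "enrichment_depletion", "rainfall")

#' Prepare the data behind a figure
#'
#' All aggregation that determines the marks of a figure — group means and
#' standard deviations, normalisation, the "display a signature only if it
#' contributes at least `threshold` in at least one sample" filter, and
#' hierarchical leaf ordering for heatmaps — happens here and is returned as
#' a table, so figures are testable at the data level and rendering is pure
#' drawing.
#'
#' @param kind One of `"spectrum"`, `"profile96"`, `"profile192"`,
#'   `"compare"`, `"contribution_bar"`, `"contribution_heatmap"`,
#'   `"cosine_heatmap"`, `"strand_bias"`, `"enrichment_depletion"`,
#'   `"rainfall"`.
#' @param inputs Named list of module outputs; see Details.
#' @param options Named list of rendering options (`mode` = "relative" or
#'   "absolute" for contribution bars, `cluster` = TRUE/FALSE and
#'   `threshold` for heatmaps).
#'
#' @details Expected `inputs` per kind: `spectrum`: `matrix` (typed spectrum
#' from [spectrum_by_type()]) and optional `groups`; `profile96`/`profile192`:
#' `matrix`; `compare`: `p1`, `p2` (named profiles); `contribution_bar` /
#' `contribution_heatmap`: `contribution`; `cosine_heatmap`: `similarity`
#' (samples x signatures); `strand_bias` / `enrichment_depletion`: `table`;
#' `rainfall`: `series` from [intermutation_distances()] plus optional
#' `chrom_lengths` for cumulative coordinates.
#'
#' @return An object of class `plot_data`: list with `kind`, `table` (a
#'   data.frame that alone determines every mark) and `options`.
#' @export
prepare_plot_data <- function(kind, inputs, options = list()) {
  if (!kind %in% PLOT_KINDS) stop("unknown plot kind: ", kind)
  tab <- switch(kind,
    spectrum = {
      m <- inputs$matrix
      groups <- inputs$groups %||% setNames(colnames(m), colnames(m))
      group_spectrum(m, groups)
    },
    profile96 = ,
    profile192 = {
      m <- inputs$matrix
      rel <- sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
      data.frame(channel = rep(rownames(m), ncol(m)),
                 sample = rep(colnames(m) %||% as.character(seq_len(ncol(m))),
                              each = nrow(m)),
                 relative_contribution = as.vector(rel),
                 count = as.vector(m), stringsAsFactors = FALSE)
    },
    compare = {
      cmp <- compare_profiles(inputs$p1, inputs$p2)
      q1 <- inputs$p1 / sum(inputs$p1); q2 <- inputs$p2 / sum(inputs$p2)
      out <- data.frame(channel = names(inputs$p1) %||% as.character(seq_along(q1)),
                        profile1 = q1, profile2 = q2,
                        difference = cmp$difference, stringsAsFactors = FALSE)
      attr(out, "rss") <- cmp$rss
      attr(out, "cosine") <- cmp$cosine
      out
    },
    contribution_bar = {
      ct <- as.matrix(inputs$contribution)
      mode <- options$mode %||% "relative"
      rel <- sweep(ct, 2, pmax(colSums(ct), .Machine$double.eps), "/")
      thr <- options$threshold %||% 0
      # a signature is displayed (for every sample) if it reaches the
      # threshold in at least one sample
      keep <- apply(rel, 1, max) >= thr
      ct <- ct[keep, , drop = FALSE]; rel <- rel[keep, , drop = FALSE]
      vals <- if (mode == "relative") rel else ct
      data.frame(signature = rep(rownames(ct), ncol(ct)),
                 sample = rep(colnames(ct) %||% as.character(seq_len(ncol(ct))),
                              each = nrow(ct)),
                 contribution = as.vector(vals), stringsAsFactors = FALSE)
    },
    contribution_heatmap = {
      ct <- as.matrix(inputs$contribution)
      rel <- sweep(ct, 2, pmax(colSums(ct), .Machine$double.eps), "/")
      thr <- options$threshold %||% 0
      keep <- apply(rel, 1, max) >= thr
      rel <- rel[keep, , drop = FALSE]
      sample_order <- colnames(rel) %||% as.character(seq_len(ncol(rel)))
      if (isTRUE(options$cluster) && ncol(rel) >= 2) {
        sample_order <- cluster_samples(t(rel))$labels
      }
      out <- data.frame(signature = rep(rownames(rel), ncol(rel)),
                        sample = rep(colnames(rel) %||% as.character(seq_len(ncol(rel))),
                                     each = nrow(rel)),
                        relative_contribution = as.vector(rel),
                        stringsAsFactors = FALSE)
      attr(out, "sample_order") <- sample_order
      out
    },
    cosine_heatmap = {
      sim <- as.matrix(inputs$similarity)
      sample_order <- rownames(sim) %||% as.character(seq_len(nrow(sim)))
      if (isTRUE(options$cluster %||% TRUE) && nrow(sim) >= 2) {
        sample_order <- cluster_samples(sim)$labels
      }
      out <- data.frame(sample = rep(rownames(sim) %||% as.character(seq_len(nrow(sim))),
                                     ncol(sim)),
                        signature = rep(colnames(sim) %||% as.character(seq_len(ncol(sim))),
                                        each = nrow(sim)),
                        cosine = as.vector(sim), stringsAsFactors = FALSE)
      attr(out, "sample_order") <- sample_order
      out
    },
    strand_bias = inputs$table,
    enrichment_depletion = inputs$table,
    rainfall = {
      ser <- inputs$series
      lens <- inputs$chrom_lengths
      if (!is.null(lens)) {
        offs <- cumsum(c(0, as.numeric(lens[-length(lens)])))
        names(offs) <- names(lens)
        ser$genome_pos <- ser$pos + offs[ser$chrom]
      } else ser$genome_pos <- ser$pos
      ser
    }
  )
  structure(list(kind = kind, table = tab, options = options),
            class = "plot_data")
}

#' @export
print.plot_data <- function(x, ...) {
  cat(sprintf("<plot_data> kind '%s': %d rows\n", x$kind, nrow(x$table)))
  invisible(x)
}

#' Render a prepared figure to file
#'
#' Pure drawing: the `plot_data` table determines every mark, and rendering
#' never alters it. Output format follows the file extension (png, pdf, svg).
#'
#' @param plot_data A `plot_data` object from [prepare_plot_data()].
#' @param path Output file path.
#' @param width,height Device size in inches.
#' @return Invisibly, `path`.
#' @export
render_plot <- function(plot_data, path, width = 8, height = 5) {
  stopifnot(inherits(plot_data, "plot_data"))
  tab <- plot_data$table
  if (is.null(tab) || nrow(tab) == 0) stop("nothing to plot")
  p <- build_ggplot(plot_data)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

build_ggplot <- function(pd) {
  tab <- pd$table
  aes <- ggplot2::aes
  switch(pd$kind,
    spectrum = ggplot2::ggplot(tab, aes(x = .data$category, y = .data$mean,
                                        fill = .data$category)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(aes(ymin = pmax(0, .data$mean - .data$sd),
                                 ymax = .data$mean + .data$sd), width = 0.3) +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(y = "relative contribution", x = NULL) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)),
    profile96 = ,
    profile192 = ggplot2::ggplot(tab, aes(x = .data$channel,
                                          y = .data$relative_contribution)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~sample, ncol = 1) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 3)),
    compare = {
      long <- data.frame(
        channel = rep(tab$channel, 3),
        panel = rep(c("profile 1", "profile 2", "difference"), each = nrow(tab)),
        value = c(tab$profile1, tab$profile2, tab$difference))
      long$panel <- factor(long$panel, c("profile 1", "profile 2", "difference"))
      ggplot2::ggplot(long, aes(x = .data$channel, y = .data$value)) +
        ggplot2::geom_col(fill = "grey30") +
        ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
        ggplot2::labs(subtitle = sprintf("RSS = %.3g, cosine = %.4f",
                                         attr(tab, "rss"), attr(tab, "cosine"))) +
        ggplot2::theme_bw() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 3))
    },
    contribution_bar = ggplot2::ggplot(tab, aes(x = .data$sample,
                                                y = .data$contribution,
                                                fill = .data$signature)) +
      ggplot2::geom_col() +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)),
    contribution_heatmap = heatmap_gg(tab, "signature", "relative_contribution"),
    cosine_heatmap = heatmap_gg(tab, "signature", "cosine"),
    strand_bias = ggplot2::ggplot(tab, aes(x = .data$type, y = .data$log2_ratio,
                                           fill = .data$type)) +
      ggplot2::geom_col() +
      ggplot2::geom_text(aes(label = ifelse(.data$significant, "*", "")),
                         vjust = 0) +
      ggplot2::facet_wrap(~group) +
      ggplot2::theme_bw(),
    enrichment_depletion = ggplot2::ggplot(tab, aes(x = .data$region,
                                                    y = .data$log2_ratio,
                                                    fill = .data$region)) +
      ggplot2::geom_col() +
      ggplot2::geom_text(aes(label = ifelse(.data$significant, "*", "")),
                         vjust = 0) +
      ggplot2::facet_wrap(~group) +
      ggplot2::theme_bw(),
    rainfall = ggplot2::ggplot(tab[!is.na(tab$distance), ],
                               aes(x = .data$genome_pos, y = .data$distance,
                                   colour = .data$type)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "genomic position", y = "intermutation distance (bp)") +
      ggplot2::theme_bw()
  )
}

heatmap_gg <- function(tab, ycol, fillcol) {
  ord <- attr(tab, "sample_order")
  if (!is.null(ord)) tab$sample <- factor(tab$sample, levels = ord)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$sample, y = .data[[ycol]],
                                    fill = .data[[fillcol]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
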