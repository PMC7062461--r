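#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_rect
#'   geom_segment geom_text scale_fill_gradient2 scale_fill_viridis_c labs
#'   theme_minimal theme element_blank
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.goku_pwm <- function(x, ...) {
  tibble(position = rep(seq_len(x$width), each = 4L),
         base = rep(BASES, x$width),
         prob = as.vector(x$prob),
         log_odds = as.vector(x$mat))
}

#' @export
glance.goku_pwm <- function(x, ...) {
  tibble(width = x$width, n_motifs = length(x$training),
         pseudocount = x$pseudocount,
         consensus = pwm_consensus(x),
         max_score = sum(apply(x$mat, 2, max)))
}

#' Heatmap of PWM log-odds
#'
#' @param object A `goku_pwm`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.goku_pwm <- function(object, ...) {
  tidy(object) %>%
    ggplot(aes(x = .data$position, y = .data$base, fill = .data$log_odds)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "site position", y = NULL, fill = "log2 odds",
         title = "dif-site position weight matrix") +
    theme_minimal()
}

#' Per-column identity profile plot
#'
#' Dips in the profile mark hypervariable regions of the alignment.
#'
#' @param object A `goku_identity_profile` from [identity_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.goku_identity_profile <- function(object, ...) {
  y <- if ("smoothed" %in% names(object)) "smoothed" else "identity"
  ggplot(object, aes(x = .data$column, y = .data[[y]])) +
    geom_line(colour = "grey30") +
    labs(x = "alignment column", y = "mean pairwise identity") +
    theme_minimal()
}

#' ANI heatmap
#'
#' @param object A `goku_ani` from [ani_matrix()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.goku_ani <- function(object, ...) {
  df <- expand.grid(id1 = object$ids, id2 = object$ids,
                    stringsAsFactors = FALSE)
  df$ani <- as.vector(object$mat)
  ggplot(df, aes(x = .data$id1, y = .data$id2, fill = .data$ani)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 100)) +
    labs(x = NULL, y = NULL, fill = "ANI (%)") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Gene map of a prophage call
#'
#' Draws the excised genome's gene calls as arrows-less blocks with the
#' phage dif position marked.
#'
#' @param object A `prophage_call` with status `"ok"`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.prophage_call <- function(object, ...) {
  stopifnot(object$status == "ok")
  genes <- object$genes
  dif_pos <- object$downstream_dif$start - object$start + 1L
  ggplot(genes) +
    geom_rect(aes(xmin = .data$start, xmax = .data$end,
                  ymin = ifelse(.data$strand == "+", 0.05, -0.45),
                  ymax = ifelse(.data$strand == "+", 0.45, -0.05),
                  fill = .data$role)) +
    geom_text(aes(x = (.data$start + .data$end) / 2,
                  y = ifelse(.data$strand == "+", 0.25, -0.25),
                  label = .data$role), size = 3) +
    geom_segment(x = dif_pos, xend = dif_pos, y = -0.6, yend = 0.6,
                 colour = "firebrick", linetype = 2) +
    labs(x = sprintf("position on excised genome (%d bp; dashed = phage dif)",
                     object$length),
         y = NULL, title = paste("prophage", object$host_id)) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), legend.position = "none")
}
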