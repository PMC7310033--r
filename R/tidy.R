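# broom-style tidiers for the package's non-tabular objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a plastome record
#'
#' One row per feature part, with the record id attached.
#'
#' @param x A [plastome()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plastome
#' @export
tidy.plastome <- function(x, ...) {
  dplyr::bind_cols(tibble(id = x$id), x$features)
}

#' @rdname tidy.plastome
#' @method glance plastome
#' @export
glance.plastome <- function(x, ...) {
  part <- x$partition
  tibble(
    id = x$id, taxon = x$taxon, length = nchar(x$seq),
    n_features = length(unique(x$features$feature_id)),
    lsc = if (is.null(part)) NA_integer_ else part$length[part$region == "LSC"],
    ira = if (is.null(part)) NA_integer_ else part$length[part$region == "IRA"],
    ssc = if (is.null(part)) NA_integer_ else part$length[part$region == "SSC"],
    irb = if (is.null(part)) NA_integer_ else part$length[part$region == "IRB"]
  )
}

#' Tidy an alignment
#'
#' @param x A [as_alignment()] alignment.
#' @param ... Unused.
#' @return `tidy()`: one row per sequence (`id`, `length`, `n_gaps`);
#'   `glance()`: the one-row [diversity_summary()].
#' @method tidy plast_aln
#' @export
tidy.plast_aln <- function(x, ...) {
  tibble(id = x$ids, length = x$length,
         n_gaps = vapply(x$seqs, function(s) {
           sum(chars(s) == "-")
         }, 0L, USE.NAMES = FALSE))
}

#' @rdname tidy.plast_aln
#' @method glance plast_aln
#' @export
glance.plast_aln <- function(x, ...) diversity_summary(x)

#' Tidy a primer pair
#'
#' @param x A [design_primer_pair()] result.
#' @param ... Unused.
#' @return One row per primer: `primer`, `sequence`, `length`, `degeneracy`,
#'   `window_start`, `window_end`.
#' @method tidy primer_pair
#' @export
tidy.primer_pair <- function(x, ...) {
  tibble(
    primer = c("forward", "reverse"),
    sequence = c(x$forward, x$reverse),
    length = nchar(c(x$forward, x$reverse)),
    degeneracy = c(primer_degeneracy(x$forward), primer_degeneracy(x$reverse)),
    window_start = c(x$fwd_window[1], x$rev_window[1]),
    window_end = c(x$fwd_window[2], x$rev_window[2])
  )
}
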