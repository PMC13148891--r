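# Batch standardization: compute per-prep input volumes that deliver the
# same amount of a chosen metric (sgRNA copies or lytic RLU) as a reference
# preparation.

#' Adjust per-prep dose volumes to match a reference preparation
#'
#' Given one quantification metric per preparation (sgRNA copies/uL from the
#' qPCR assay, or RLU/uL from the lytic HiBiT assay), computes the input
#' volume of each prep that delivers the same metric amount as
#' `ref_volume` uL of the reference prep:
#' `volume_i = ref_volume * value_ref / value_i`, after rescaling values
#' measured at different dilutions to a common undiluted basis
#' (`value * dilution`). Volumes above `max_volume` are capped and flagged;
#' preps with a zero metric cannot be normalized and are excluded (volume
#' `NA`, flagged).
#'
#' @param metrics data.frame with columns `prep`, `value`, and optionally
#'   `dilution` (measurement dilution factor, default 1) and `kind` (must be
#'   a single metric kind if present)
#' @param reference prep id of the reference preparation
#' @param ref_volume dose volume of the reference prep in uL (default 1)
#' @param max_volume optional cap on adjusted volumes in uL (default `Inf`)
#' @return `dose_adjustment` object: data.frame `doses` with `prep`,
#'   `volume_ul`, `delivered` (volume x undiluted value), `capped`, `flag`,
#'   plus `reference`, `ref_volume`, `ref_amount`
#' @export
adjust_doses <- function(metrics, reference, ref_volume = 1,
                         max_volume = Inf) {
  stopifnot(all(c("prep", "value") %in% names(metrics)))
  if (!"dilution" %in% names(metrics)) metrics$dilution <- 1
  if ("kind" %in% names(metrics) && length(unique(metrics$kind)) > 1)
    stop("all metrics must share one kind; got: ",
         paste(unique(metrics$kind), collapse = ", "))
  if (any(metrics$value < 0)) stop("metric values must be non-negative")
  if (any(metrics$dilution < 1)) stop("dilution factors must be >= 1")
  if (!reference %in% metrics$prep)
    stop("reference prep '", reference, "' not found in metrics")
  if (ref_volume <= 0) stop("'ref_volume' must be positive")
  undiluted <- metrics$value * metrics$dilution
  ref_value <- undiluted[match(reference, metrics$prep)]
  if (ref_value <= 0) stop("reference prep has zero metric value")
  volume <- ref_volume * ref_value / undiluted
  flag <- rep("", nrow(metrics))
  nonnorm <- undiluted == 0
  volume[nonnorm] <- NA_real_
  flag[nonnorm] <- "non_normalizable"
  capped <- !nonnorm & volume > max_volume
  volume[capped] <- max_volume
  flag[capped] <- "capped"
  doses <- data.frame(prep = metrics$prep, volume_ul = volume,
                      delivered = volume * undiluted, capped = capped,
                      flag = flag, stringsAsFactors = FALSE)
  structure(list(doses = doses, reference = reference,
                 ref_volume = ref_volume,
                 ref_amount = ref_volume * ref_value),
            class = "dose_adjustment")
}

#' @export
print.dose_adjustment <- function(x, ...) {
  cat(sprintf("<dose adjustment> reference %s at %.2f uL (amount %.4g)\n",
              x$reference, x$ref_volume, x$ref_amount))
  d <- x$doses
  d$volume_ul <- round(d$volume_ul, 2)  # pipettable precision for display
  print(d, row.names = FALSE)
  invisible(x)
}

#' Delivered metric amount per preparation
#'
#' Verification view of a dose adjustment: volume times undiluted metric
#' value per prep. Uncapped preps all deliver exactly the reference amount
#' by construction; capped preps deliver less and keep their flag.
#'
#' @param adjustment a [adjust_doses()] result
#' @return data.frame with `prep`, `delivered`, `flag`
#' @export
delivered_amount <- function(adjustment) {
  stopifnot(inherits(adjustment, "dose_adjustment"))
  adjustment$doses[, c("prep", "delivered", "flag")]
}
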