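# Absolute sgRNA copy-number quantification from qPCR plates: replicate QC,
# standard-curve fitting in the slope-intercept form y = m*Ct + b with
# y = log10(ng of template), conversion of ng to molecule copies, and the
# four-step scaling from copies per uL of qPCR reaction to copies per uL of
# eVLP preparation. Also relative plasmid load per genome against an
# internal control gene.

#' Workflow parameters for copy-number extrapolation
#'
#' Constants and volume factors of the copy-number formula and the four-step
#' scaling chain: copies = ng x N_A / (L x 330 g/mol x 1e9 ng/g), then
#' reaction-level copies are multiplied by the cDNA dilution factor and the
#' cDNA synthesis reaction volume, divided by the RNA volume used in cDNA
#' synthesis, multiplied by the RNA elution volume, and divided by the prep
#' volume extracted.
#'
#' @param amplicon_bp amplicon length in bp (default 69, the scaffold assay)
#' @param cdna_dilution fold dilution of the cDNA used in the reaction
#'   (10 or 100; default 100)
#' @param cdna_volume_ul cDNA synthesis reaction volume in uL (default 20)
#' @param rna_volume_ul volume of eVLP RNA used in cDNA synthesis, uL
#'   (sample-specific, normalized to 100 ng input; default 4)
#' @param elution_volume_ul RNA extraction elution volume, uL (default 30)
#' @param prep_volume_ul volume of eVLP preparation extracted, uL (default 5)
#' @param avogadro Avogadro's number, molecules/mol
#' @param g_per_mol_nt average molecular weight of one nt of ssDNA, g/mol
#' @param ng_per_g nanogram-to-gram conversion factor
#' @return `workflow_params` object (a validated list)
#' @export
workflow_params <- function(amplicon_bp = 69,
                            cdna_dilution = 100,
                            cdna_volume_ul = 20,
                            rna_volume_ul = 4,
                            elution_volume_ul = 30,
                            prep_volume_ul = 5,
                            avogadro = 6.022e23,
                            g_per_mol_nt = 330,
                            ng_per_g = 1e9) {
  p <- list(amplicon_bp = amplicon_bp, cdna_dilution = cdna_dilution,
            cdna_volume_ul = cdna_volume_ul, rna_volume_ul = rna_volume_ul,
            elution_volume_ul = elution_volume_ul,
            prep_volume_ul = prep_volume_ul, avogadro = avogadro,
            g_per_mol_nt = g_per_mol_nt, ng_per_g = ng_per_g)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0)
    stop("workflow parameters must be single positive numbers; offending: ",
         paste(bad, collapse = ", "))
  if (p$cdna_dilution < 1) stop("'cdna_dilution' must be >= 1")
  structure(p, class = "workflow_params")
}

#' Replicate quality control on Ct values
#'
#' Applies the replicate-dispersion rule: if the standard deviation of the
#' Ct replicates exceeds `sd_threshold` cycles, the single value farthest
#' from the median is discarded and the group re-tested; at most one value
#' is removed, and a group still exceeding the threshold is marked invalid
#' and excluded from curves and quantification. Non-detects are `NA` and are
#' never imputed.
#'
#' @param ct numeric vector of Ct values (`NA` = non-detect)
#' @param sd_threshold maximum allowed replicate SD in cycles (default 0.5)
#' @return list with `kept` (numeric), `removed` (numeric), `valid`
#'   (logical), and `flags` (character vector of QC annotations)
#' @export
filter_replicates <- function(ct, sd_threshold = 0.5) {
  if (sd_threshold <= 0) stop("'sd_threshold' must be positive")
  flags <- character(0)
  vals <- ct[!is.na(ct)]
  if (any(vals <= 0)) stop("Ct values must be positive")
  if (length(vals) == 0)
    return(list(kept = numeric(0), removed = numeric(0), valid = FALSE,
                flags = "all_nd"))
  if (length(vals) < length(ct)) flags <- c(flags, "nd_dropped")
  if (length(vals) == 1)
    return(list(kept = vals, removed = numeric(0), valid = TRUE,
                flags = c(flags, "singleton")))
  if (stats::sd(vals) <= sd_threshold)
    return(list(kept = vals, removed = numeric(0), valid = TRUE,
                flags = flags))
  drop <- which.max(abs(vals - stats::median(vals)))
  removed <- vals[drop]
  kept <- vals[-drop]
  flags <- c(flags, sprintf("outlier_removed:%.3g", removed))
  if (length(kept) >= 2 && stats::sd(kept) > sd_threshold) {
    return(list(kept = numeric(0), removed = removed, valid = FALSE,
                flags = c(flags, "sd_exceeds_threshold")))
  }
  list(kept = kept, removed = removed, valid = TRUE, flags = flags)
}

#' Describe a serial dilution series of the quantification standard
#'
#' Concentrations are inferred from a single measured anchor dilution by
#' assuming an exact `fold`-step decrease between consecutive steps.
#'
#' @param anchor_ng template mass (ng per reaction) at the anchor step
#' @param n_steps number of dilution steps in the series
#' @param fold dilution factor between steps (default 10)
#' @param labels optional step labels (default `"d1".."dN"`, most
#'   concentrated first)
#' @param anchor_step index of the step whose concentration was measured
#' @return data.frame with columns `dilution` (label) and `ng`
#' @export
dilution_series <- function(anchor_ng, n_steps, fold = 10,
                            labels = NULL, anchor_step = 1L) {
  if (anchor_ng <= 0 || fold <= 1 || n_steps < 2)
    stop("need anchor_ng > 0, fold > 1, n_steps >= 2")
  if (is.null(labels)) labels <- paste0("d", seq_len(n_steps))
  if (length(labels) != n_steps) stop("'labels' must have length n_steps")
  ng <- anchor_ng * fold^(anchor_step - seq_len(n_steps))
  data.frame(dilution = labels, ng = ng, stringsAsFactors = FALSE)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of y = log10(ng of standard) on x = mean Ct per
#' dilution step, after replicate QC. The amplification efficiency derives
#' from the slope as `10^(-m) - 1` (1.0 = perfect doubling each cycle).
#'
#' @param standards data.frame with columns `dilution` and `ct` (one row per
#'   replicate; `NA` ct = non-detect)
#' @param series dilution series as returned by [dilution_series()]
#' @param sd_threshold replicate QC threshold passed to [filter_replicates()]
#' @return `standard_curve` object with fields `m`, `b`, `r_squared`,
#'   `efficiency`, `n_points`, `ct_range`, `flags`
#' @export
fit_standard_curve <- function(standards, series, sd_threshold = 0.5) {
  stopifnot(all(c("dilution", "ct") %in% names(standards)),
            all(c("dilution", "ng") %in% names(series)))
  pts <- lapply(seq_len(nrow(series)), function(i) {
    lab <- series$dilution[i]
    cts <- standards$ct[standards$dilution == lab]
    if (length(cts) == 0) return(NULL)
    qc <- filter_replicates(cts, sd_threshold)
    if (!qc$valid || length(qc$kept) == 0) return(NULL)
    data.frame(dilution = lab, ct = mean(qc$kept), ng = series$ng[i])
  })
  pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(pts) || nrow(pts) < 3)
    stop("fewer than 3 valid dilution points; cannot fit a standard curve")
  flags <- character(0)
  if (is.unsorted(pts$ct[order(pts$ng, decreasing = TRUE)]))
    flags <- c(flags, "nonmonotonic_ct")
  fit <- stats::lm(log10(ng) ~ ct, data = pts)
  m <- unname(stats::coef(fit)[["ct"]])
  b <- unname(stats::coef(fit)[["(Intercept)"]])
  # suppress the "essentially perfect fit" note on noiseless input
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (m >= 0) flags <- c(flags, "nonnegative_slope")
  structure(list(m = m, b = b, r_squared = r2,
                 efficiency = 10^(-m) - 1, n_points = nrow(pts),
                 ct_range = range(pts$ct), flags = flags,
                 points = pts),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard curve> log10(ng) = %.4f * Ct + %.3f | R^2 = %.4f | eff = %.1f%% | n = %d\n",
    x$m, x$b, x$r_squared, 100 * x$efficiency, x$n_points))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a Ct value to template mass via a standard curve
#'
#' The antilog of the curve: ng = 10^(m*Ct + b). Ct values outside the
#' fitted standard range are extrapolated and flagged in the
#' `"extrapolated"` attribute.
#'
#' @param ct Ct value(s)
#' @param curve a [fit_standard_curve()] result
#' @return ng of test sample (numeric, same length as `ct`)
#' @export
ct_to_ng <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  out <- 10^(curve$m * ct + curve$b)
  attr(out, "extrapolated") <- ct < curve$ct_range[1] | ct > curve$ct_range[2]
  out
}

#' Convert template mass to molecule copies
#'
#' copies = ng x N_A / (amplicon length x 330 g/mol x 1e9 ng/g).
#'
#' @param ng template mass in ng (per uL of reaction)
#' @param params a [workflow_params()] object
#' @return copies per uL of qPCR reaction
#' @export
ng_to_copies <- function(ng, params = workflow_params()) {
  stopifnot(inherits(params, "workflow_params"))
  if (any(ng < 0, na.rm = TRUE)) stop("'ng' must be non-negative")
  ng * params$avogadro /
    (params$amplicon_bp * params$g_per_mol_nt * params$ng_per_g)
}

#' Scale reaction-level copies to copies per uL of preparation
#'
#' The four-step chain: multiply by the cDNA dilution factor and the cDNA
#' synthesis volume, divide by the RNA volume used in cDNA synthesis,
#' multiply by the RNA elution volume, divide by the prep volume extracted.
#' The dilution correction is applied exactly once, here.
#'
#' @param copies_rxn copies per uL of qPCR reaction
#' @param params a [workflow_params()] object
#' @return `prep_titer` object with `copies_rxn`, `copies_per_ul_prep`,
#'   and the `params` used
#' @export
copies_per_ul_prep <- function(copies_rxn, params = workflow_params()) {
  stopifnot(inherits(params, "workflow_params"))
  if (any(copies_rxn < 0, na.rm = TRUE))
    stop("'copies_rxn' must be non-negative")
  titer <- copies_rxn * params$cdna_dilution * params$cdna_volume_ul /
    params$rna_volume_ul * params$elution_volume_ul / params$prep_volume_ul
  structure(list(copies_rxn = copies_rxn, copies_per_ul_prep = titer,
                 params = params),
            class = "prep_titer")
}

#' @export
print.prep_titer <- function(x, ...) {
  cat(sprintf("<prep titer> %.4g copies/uL reaction -> %.4g copies/uL prep\n",
              x$copies_rxn[1], x$copies_per_ul_prep[1]))
  invisible(x)
}

#' Quantify one test sample end to end
#'
#' Replicate QC, Ct-to-ng via the standard curve, ng-to-copies, and the
#' four-step scaling to copies per uL of preparation.
#'
#' @param ct Ct replicates of the test sample (`NA` = non-detect)
#' @param curve a [fit_standard_curve()] result
#' @param params a [workflow_params()] object
#' @param sd_threshold replicate QC threshold in cycles
#' @return list with `copies_rxn`, `copies_per_ul_prep`, `mean_ct`, `ng`,
#'   `valid`, `flags`
#' @export
quantify_sample <- function(ct, curve, params = workflow_params(),
                            sd_threshold = 0.5) {
  qc <- filter_replicates(ct, sd_threshold)
  if (!qc$valid || length(qc$kept) == 0) {
    return(list(copies_rxn = NA_real_, copies_per_ul_prep = NA_real_,
                mean_ct = NA_real_, ng = NA_real_, valid = FALSE,
                flags = qc$flags))
  }
  mean_ct <- mean(qc$kept)
  ng <- ct_to_ng(mean_ct, curve)
  flags <- qc$flags
  if (isTRUE(attr(ng, "extrapolated"))) flags <- c(flags, "extrapolated")
  copies <- ng_to_copies(as.numeric(ng), params)
  titer <- copies_per_ul_prep(copies, params)
  list(copies_rxn = copies, copies_per_ul_prep = titer$copies_per_ul_prep,
       mean_ct = mean_ct, ng = as.numeric(ng), valid = TRUE, flags = flags)
}

#' Relative plasmid load per 100 genomes
#'
#' Plasmid and internal-control copies are each quantified against their own
#' standard curve (with each assay's amplicon length); genome equivalents
#' are the control copies divided by the assumed control copies per genome
#' (2 for an autosomal gene in a diploid genome), and the plasmid load is
#' reported per 100 genomes.
#'
#' @param plasmid_ct,control_ct Ct replicates for the plasmid assay and the
#'   control-gene assay (`NA` = non-detect)
#' @param plasmid_curve,control_curve their standard curves
#' @param plasmid_params,control_params their [workflow_params()] (amplicon
#'   lengths differ between assays)
#' @param control_copies_per_genome copies of the control locus per genome
#'   (default 2)
#' @param sd_threshold replicate QC threshold
#' @return list with `copies_per_100_genomes`, `plasmid_copies`,
#'   `control_copies`, `genomes`, `valid`, `flags`
#' @export
plasmid_load_per_genome <- function(plasmid_ct, control_ct,
                                    plasmid_curve, control_curve,
                                    plasmid_params, control_params,
                                    control_copies_per_genome = 2,
                                    sd_threshold = 0.5) {
  if (control_copies_per_genome <= 0)
    stop("'control_copies_per_genome' must be positive")
  ctrl_qc <- filter_replicates(control_ct, sd_threshold)
  if (!ctrl_qc$valid || length(ctrl_qc$kept) == 0) {
    return(list(copies_per_100_genomes = NA_real_, plasmid_copies = NA_real_,
                control_copies = NA_real_, genomes = NA_real_, valid = FALSE,
                flags = c("control_non_quantifiable", ctrl_qc$flags)))
  }
  ctrl_copies <- ng_to_copies(
    as.numeric(ct_to_ng(mean(ctrl_qc$kept), control_curve)), control_params)
  genomes <- ctrl_copies / control_copies_per_genome
  plas_qc <- filter_replicates(plasmid_ct, sd_threshold)
  if (!plas_qc$valid || length(plas_qc$kept) == 0) {
    return(list(copies_per_100_genomes = 0, plasmid_copies = 0,
                control_copies = ctrl_copies, genomes = genomes,
                valid = TRUE, flags = c("plasmid_nd", plas_qc$flags)))
  }
  plas_copies <- ng_to_copies(
    as.numeric(ct_to_ng(mean(plas_qc$kept), plasmid_curve)), plasmid_params)
  list(copies_per_100_genomes = 100 * plas_copies / genomes,
       plasmid_copies = plas_copies, control_copies = ctrl_copies,
       genomes = genomes, valid = TRUE,
       flags = c(plas_qc$flags, ctrl_qc$flags))
}

#' Read a long-format qPCR plate export
#'
#' Expected columns: `sample`, `target`, `role` (one of standard, test,
#' noRT, NTC), `dilution`, `replicate`, `ct`; the literal string `"ND"` (or
#' an empty field) in `ct` is read as a non-detect.
#'
#' @param file CSV path
#' @return data.frame with `ct` numeric (`NA` = non-detect)
#' @export
read_plate <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample", "target", "role", "dilution", "replicate", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("plate file is missing column(s): ", paste(missing, collapse = ", "))
  ct <- trimws(as.character(df$ct))
  ct[ct %in% c("ND", "nd", "")] <- NA
  df$ct <- as.numeric(ct)
  df
}
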