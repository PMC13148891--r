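# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, so each stage can be tested end to end. All generators are
# deterministic under a seed. Defaults emulate the study conditions: 10-fold
# standard dilution series run in triplicate, prep titers in the 10^6
# copies/uL range, Ct noise SD 0.15 cycles, no-RT signal 20-26-fold below
# the test signal, sigmoidal (logistic) per-well luminescence with a small
# pre-treatment baseline and ~10% multiplicative measurement noise.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

#' True standard curve from an amplification efficiency
#'
#' Helper converting a per-cycle amplification efficiency to the slope of
#' the log10(ng)-on-Ct curve: m = -log10(1 + efficiency).
#'
#' @param efficiency fractional efficiency in (0, 1]
#' @param b curve intercept (log10 ng at Ct 0)
#' @return list with `m`, `b`, `efficiency`
#' @export
true_curve <- function(efficiency = 0.95, b = 1.5) {
  if (efficiency <= 0 || efficiency > 1)
    stop("'efficiency' must be in (0, 1]")
  list(m = -log10(1 + efficiency), b = b, efficiency = efficiency)
}

#' Simulate a standard dilution series
#'
#' Generates triplicate Ct rows for an `n_points`-step `fold`-fold dilution
#' series under a known true curve: Ct = (log10(ng) - b)/m + N(0, ct_sd).
#'
#' @param curve a [true_curve()] (true slope/intercept generating the Cts)
#' @param anchor_ng ng of standard at the most concentrated step
#' @param n_points number of dilution steps (default 7)
#' @param fold dilution factor between steps (default 10)
#' @param ct_sd Gaussian Ct noise SD in cycles (default 0.15)
#' @param n_reps replicates per step (default 3)
#' @param seed RNG seed (NULL = use current RNG state)
#' @return list with `plate` (long data.frame of standard rows), `series`
#'   (the [dilution_series()]), and `truth` (the generating curve)
#' @export
gen_standard_series <- function(curve = true_curve(), anchor_ng = 1,
                                n_points = 7, fold = 10, ct_sd = 0.15,
                                n_reps = 3, seed = NULL) {
  if (n_points < 3) stop("'n_points' must be >= 3")
  series <- dilution_series(anchor_ng, n_points, fold)
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_points), function(i) {
      ct_true <- (log10(series$ng[i]) - curve$b) / curve$m
      data.frame(sample = "standard", target = "scaffold", role = "standard",
                 dilution = series$dilution[i], replicate = seq_len(n_reps),
                 ct = ct_true + stats::rnorm(n_reps, 0, ct_sd),
                 stringsAsFactors = FALSE)
    }))
    list(plate = rows, series = series, truth = curve)
  })
}

#' Simulate test-prep qPCR rows from a known titer
#'
#' Inverts the four-step scaling chain and the copy-number formula to the
#' expected ng per reaction for each prep's true titer, converts to a true
#' Ct via the generating curve, adds Gaussian noise, and emits triplicates
#' plus a no-RT control row set at `no_rt_fold`-fold lower signal
#' (plasmid-carryover background).
#'
#' @param true_titer true copies per uL of preparation (recycled over preps)
#' @param curve a [true_curve()]
#' @param params a [workflow_params()]
#' @param n_preps number of preparations
#' @param ct_sd Gaussian Ct noise SD in cycles
#' @param no_rt_fold fold reduction of the no-RT signal; a length-2 vector
#'   is sampled uniformly per prep (default c(20, 26))
#' @param n_reps replicates per sample
#' @param seed RNG seed
#' @return list with `plate` (test and noRT rows) and `truth`
#'   (per-prep data.frame: prep, copies_per_ul_prep, ng_rxn, ct_true,
#'   no_rt_fold)
#' @export
gen_prep_samples <- function(true_titer = 6e6, curve = true_curve(),
                             params = workflow_params(), n_preps = 3,
                             ct_sd = 0.15, no_rt_fold = c(20, 26),
                             n_reps = 3, seed = NULL) {
  stopifnot(inherits(params, "workflow_params"))
  titers <- rep_len(true_titer, n_preps)
  chain <- params$cdna_dilution * params$cdna_volume_ul /
    params$rna_volume_ul * params$elution_volume_ul / params$prep_volume_ul
  copies_rxn <- titers / chain
  ng <- copies_rxn * params$amplicon_bp * params$g_per_mol_nt *
    params$ng_per_g / params$avogadro
  ct_true <- (log10(ng) - curve$b) / curve$m
  with_seed(seed, {
    folds <- if (length(no_rt_fold) == 2)
      stats::runif(n_preps, no_rt_fold[1], no_rt_fold[2])
    else rep_len(no_rt_fold, n_preps)
    rows <- do.call(rbind, lapply(seq_len(n_preps), function(i) {
      prep <- sprintf("prep%02d", i)
      ct_nort <- (log10(ng[i] / folds[i]) - curve$b) / curve$m
      rbind(
        data.frame(sample = prep, target = "scaffold", role = "test",
                   dilution = "test", replicate = seq_len(n_reps),
                   ct = ct_true[i] + stats::rnorm(n_reps, 0, ct_sd),
                   stringsAsFactors = FALSE),
        data.frame(sample = prep, target = "scaffold", role = "noRT",
                   dilution = "test", replicate = seq_len(n_reps),
                   ct = ct_nort + stats::rnorm(n_reps, 0, ct_sd),
                   stringsAsFactors = FALSE))
    }))
    truth <- data.frame(prep = sprintf("prep%02d", seq_len(n_preps)),
                        copies_per_ul_prep = titers, ng_rxn = ng,
                        ct_true = ct_true, no_rt_fold = folds,
                        stringsAsFactors = FALSE)
    list(plate = rows, truth = truth)
  })
}

#' Default live-cell sampling grid
#'
#' Baseline at -1 h, treatment at 0 h, readings every 5 min for the first
#' hour and every 30 min thereafter up to `t_end`.
#'
#' @param t_end last time point in hours (default 5)
#' @return numeric vector of times in hours
#' @export
default_time_grid <- function(t_end = 5) {
  c(-1, seq(0, 1, by = 5 / 60), seq(1.5, t_end, by = 0.5))
}

#' Simulate live-cell luminescence time courses
#'
#' Per-well signal follows a logistic transduction curve on top of a small
#' pre-treatment baseline, with a lognormal well scale factor and
#' multiplicative measurement noise:
#' `RLU(t) = scale * (baseline + L_eff / (1 + exp(-k (t - t50)))) * noise`.
#' The effective plateau `L_eff` scales proportionally with dose up to a
#' saturation cap, and is divided by `lum_factor` for inhibitor conditions.
#' The baseline row (time < 0) carries only `scale * baseline * noise`.
#'
#' @param conditions data.frame with columns `condition` and optionally
#'   `dose_ul` (default 1) and `lum_factor` (signal divisor, default 1;
#'   e.g. 4 for an endosomal-acidification inhibitor)
#' @param plateau_rlu logistic plateau L for a 1-uL dose (default 1e5)
#' @param rate_per_h logistic rate k per hour (default 3)
#' @param midpoint_h logistic midpoint t50 in hours (default 1)
#' @param baseline_rlu pre-treatment background RLU (default 100)
#' @param sat_cap_ul dose above which L no longer scales (default 5)
#' @param scale_sdlog lognormal SD of the per-well scale factor (default 0.2)
#' @param rlu_cv multiplicative measurement noise CV (default 0.1; 0 = none)
#' @param n_wells replicate wells per condition (default 3)
#' @param times sampling grid in hours (default [default_time_grid()])
#' @param seed RNG seed
#' @return list with `wells` (long data.frame: well, condition, time_h, rlu)
#'   and `truth` (per-condition effective parameters)
#' @export
gen_timecourses <- function(conditions = data.frame(condition = "eVLP"),
                            plateau_rlu = 1e5, rate_per_h = 3,
                            midpoint_h = 1, baseline_rlu = 100,
                            sat_cap_ul = 5, scale_sdlog = 0.2, rlu_cv = 0.1,
                            n_wells = 3, times = default_time_grid(),
                            seed = NULL) {
  stopifnot("condition" %in% names(conditions))
  if (!"dose_ul" %in% names(conditions)) conditions$dose_ul <- 1
  if (!"lum_factor" %in% names(conditions)) conditions$lum_factor <- 1
  L_eff <- plateau_rlu * pmin(conditions$dose_ul, sat_cap_ul) /
    conditions$lum_factor
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(conditions))) {
      for (w in seq_len(n_wells)) {
        scale <- stats::rlnorm(1, 0, scale_sdlog)
        signal <- ifelse(times < 0, 0,
                         L_eff[i] / (1 + exp(-rate_per_h *
                                               (times - midpoint_h))))
        mu <- scale * (baseline_rlu + signal)
        noise <- if (rlu_cv > 0)
          stats::rlnorm(length(times), -log(1 + rlu_cv^2) / 2,
                        sqrt(log(1 + rlu_cv^2)))
        else 1
        rows[[length(rows) + 1L]] <- data.frame(
          well = sprintf("%s_w%d", conditions$condition[i], w),
          condition = conditions$condition[i], time_h = times,
          rlu = mu * noise, stringsAsFactors = FALSE)
      }
    }
    truth <- data.frame(condition = conditions$condition,
                        dose_ul = conditions$dose_ul,
                        lum_factor = conditions$lum_factor, L_eff = L_eff,
                        rate_per_h = rate_per_h, midpoint_h = midpoint_h,
                        baseline_rlu = baseline_rlu, stringsAsFactors = FALSE)
    list(wells = do.call(rbind, rows), truth = truth)
  })
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Reverse-translate a peptide with random codon choices
#'
#' @param peptide amino-acid string (standard alphabet)
#' @param seed RNG seed
#' @return DNA string of length `3 * nchar(peptide)`
#' @export
reverse_translate <- function(peptide, seed = NULL) {
  peptide <- check_query(peptide)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    paste(vapply(chars, function(a) {
      opts <- CODON_TABLE[[a]]
      opts[sample.int(length(opts), 1)]
    }, character(1)), collapse = "")
  })
}

#' Simulate a plasmid sequence with a planted peptide motif
#'
#' A random A/C/G/T background into which the query peptide (optionally
#' carrying `n_mutations` random residue substitutions) is reverse-
#' translated with random codons and planted at a chosen frame and peptide
#' offset. The annotation records where the scanners must find it.
#'
#' @param peptide peptide to plant (default the bundled HiBiT query)
#' @param length_nt total sequence length (>= 3*query length + 6)
#' @param frame target frame, one of +1,+2,+3,-1,-2,-3
#' @param offset 0-based peptide offset of the planted window in that frame
#' @param n_mutations number of residue substitutions applied before
#'   planting (default 0)
#' @param id record id
#' @param seed RNG seed
#' @return list with `seq`, `id`, and `annotation` (frame, offset,
#'   nt_start on the forward strand, planted peptide, n_mutations)
#' @export
gen_plasmid_with_motif <- function(peptide = hibit_query(), length_nt = 600,
                                   frame = 1L, offset = 0L,
                                   n_mutations = 0L, id = "synthetic_plasmid",
                                   seed = NULL) {
  peptide <- check_query(peptide)
  k <- nchar(peptide)
  if (length_nt < 3 * k + 6)
    stop("'length_nt' must be at least 3*query length + 6")
  if (!frame %in% FRAME_ORDER) stop("'frame' must be one of +1,+2,+3,-1,-2,-3")
  # insertion start on the translated strand, 0-based
  ins <- (abs(frame) - 1L) + 3L * offset
  if (ins + 3L * k > length_nt)
    stop("offset/frame incompatible with 'length_nt': planted window ",
         "would extend past the sequence end")
  with_seed(seed, {
    planted <- peptide
    if (n_mutations > 0) {
      chars <- strsplit(planted, "", fixed = TRUE)[[1]]
      pos <- sample.int(k, n_mutations)
      for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
      planted <- paste(chars, collapse = "")
    }
    cassette <- reverse_translate(planted)
    background <- paste(sample(c("A", "C", "G", "T"), length_nt,
                               replace = TRUE), collapse = "")
    strand <- background
    substr(strand, ins + 1L, ins + 3L * k) <- cassette
    seq <- if (frame > 0) strand else revcomp(strand)
    nt_start <- if (frame > 0) ins else length_nt - ins - 3L
    list(seq = seq, id = id,
         annotation = list(frame = as.integer(frame),
                           offset = as.integer(offset),
                           nt_start = as.integer(nt_start),
                           peptide = planted,
                           n_mutations = as.integer(n_mutations)))
  })
}
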