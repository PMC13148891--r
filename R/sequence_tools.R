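# Six-frame translation, HiBiT-like motif scanning, in-silico PCR, and
# peptide mass. Coordinates are 0-based, half-open, on the forward strand
# throughout; frames are +1,+2,+3 (forward) and -1,-2,-3 (reverse
# complement). Frame ordering for tie-breaks is +1,+2,+3,-1,-2,-3.

FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average (isotope-abundance-weighted) residue masses in Da; a free peptide
# adds one water (18.02 Da).
AA_AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

check_dna <- function(seq, alphabet = IUPAC_DNA, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% alphabet))
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-%s character '%s' at position %d",
                 what, if (length(alphabet) == 4) "ACGT" else "IUPAC-DNA",
                 chars[bad[1]], bad[1]))
  }
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # any codon with a non-ACGT base
  aa
}

#' Translate a DNA sequence in all six reading frames
#'
#' Whole-frame conceptual translation (not ORF finding): stop codons are
#' rendered `*` and translation continues through them; codons containing
#' any non-ACGT (IUPAC ambiguity) base are rendered `X`. Each translation
#' carries an offset map from peptide position to the 0-based forward-strand
#' nucleotide start of the corresponding codon, so hits on reverse frames
#' can be reported in forward coordinates.
#'
#' @param seq DNA string (IUPAC alphabet, length >= 3)
#' @param id source identifier recorded on each translation
#' @return list of six `frame_translation` objects (frames +1,+2,+3,-1,-2,-3),
#'   each a list with `source`, `frame`, `peptide`, and `nt_start` (integer
#'   vector, one 0-based codon start per residue)
#' @export
translate_six_frames <- function(seq, id = "seq") {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 3)
    stop("'seq' must be a single DNA string of at least 3 nucleotides")
  seq <- check_dna(seq, IUPAC_DNA, "sequence")
  n <- nchar(seq)
  rc <- revcomp(seq)
  lapply(FRAME_ORDER, function(f) {
    off <- abs(f) - 1L             # 0-based offset on the translated strand
    template <- if (f > 0) seq else rc
    n_codons <- (n - off) %/% 3L
    if (n_codons == 0) {
      return(structure(list(source = id, frame = f, peptide = "",
                            nt_start = integer(0)),
                       class = "frame_translation"))
    }
    starts <- off + 3L * (seq_len(n_codons) - 1L)   # 0-based on template
    codons <- substring(template, starts + 1L, starts + 3L)
    pep <- paste(translate_codons(codons), collapse = "")
    nt_start <- if (f > 0) starts else n - starts - 3L
    structure(list(source = id, frame = f, peptide = pep,
                   nt_start = as.integer(nt_start)),
              class = "frame_translation")
  })
}

#' @export
print.frame_translation <- function(x, ...) {
  cat(sprintf("<frame %+d of %s> %d aa\n", x$frame, x$source,
              nchar(x$peptide)))
  invisible(x)
}

empty_hits <- function() {
  data.frame(source = character(0), frame = integer(0),
             pep_offset = integer(0), nt_start = integer(0),
             window = character(0), mode = character(0),
             distance = integer(0), stringsAsFactors = FALSE)
}

check_query <- function(query) {
  if (!is.character(query) || length(query) != 1 || nchar(query) == 0)
    stop("'query' must be a single non-empty peptide string")
  query <- toupper(query)
  chars <- strsplit(query, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA20))
  if (length(bad) > 0)
    stop(sprintf("query contains nonstandard residue '%s' at position %d",
                 chars[bad[1]], bad[1]))
  query
}

frame_rank <- function(frame) match(frame, FRAME_ORDER)

sort_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$distance, hits$source, frame_rank(hits$frame),
               hits$pep_offset)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Shared sliding-window scanner. `dist_fun` receives the character matrix of
# windows (rows = window position 1..k, cols = windows) and the query
# character vector, and returns an integer distance per window. Windows
# containing a stop are never reported; 'X' handling is up to dist_fun.
scan_frames <- function(frames, query, mode, max_distance, dist_fun) {
  if (inherits(frames, "frame_translation")) frames <- list(frames)
  k <- nchar(query)
  qchars <- strsplit(query, "", fixed = TRUE)[[1]]
  res <- lapply(frames, function(fr) {
    pep <- fr$peptide
    n <- nchar(pep)
    if (n < k) return(NULL)
    chars <- strsplit(pep, "", fixed = TRUE)[[1]]
    n_win <- n - k + 1L
    # rows: position within window; cols: window start
    win <- vapply(seq_len(k),
                  function(j) chars[j:(j + n_win - 1L)],
                  character(n_win))
    win <- t(matrix(win, nrow = n_win))
    has_stop <- colSums(win == "*") > 0
    d <- dist_fun(win, qchars)
    keep <- !has_stop & d <= max_distance
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    data.frame(source = fr$source, frame = fr$frame,
               pep_offset = idx - 1L,
               nt_start = fr$nt_start[idx],
               window = substring(pep, idx, idx + k - 1L),
               mode = mode, distance = as.integer(d[idx]),
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(empty_hits())
  sort_hits(do.call(rbind, res))
}

hamming_dist_fun <- function(win, qchars) {
  # 'X' never equals a query residue, so it counts as a mismatch
  colSums(win != qchars)
}

#' Exact motif scan over frame translations
#'
#' Reports every window identical to the query (distance 0). Windows
#' containing `*` (stop) or `X` (untranslatable codon) never match.
#'
#' @param frames list of `frame_translation` objects (see
#'   [translate_six_frames()])
#' @param query peptide string, standard 20-letter alphabet
#' @return data.frame of hits with columns `source`, `frame`, `pep_offset`
#'   (0-based), `nt_start` (0-based forward strand), `window`, `mode`,
#'   `distance`, sorted by (distance, source, frame, offset)
#' @export
scan_exact <- function(frames, query) {
  query <- check_query(query)
  scan_frames(frames, query, "exact", 0L, hamming_dist_fun)
}

#' Hamming-distance fuzzy motif scan
#'
#' Reports every window whose Hamming distance to the query is at most
#' `max_distance`. `X` counts as a mismatch at its position; windows
#' containing `*` are excluded.
#'
#' @inheritParams scan_exact
#' @param max_distance maximum number of mismatching positions (default 3)
#' @return data.frame of hits (see [scan_exact()])
#' @export
scan_hamming <- function(frames, query, max_distance = 3L) {
  query <- check_query(query)
  if (!is.numeric(max_distance) || length(max_distance) != 1 ||
      max_distance < 0)
    stop("'max_distance' must be a single non-negative integer")
  scan_frames(frames, query, "hamming", as.integer(max_distance),
              hamming_dist_fun)
}

#' Default biochemical-property alphabet
#'
#' Five-class reduced alphabet used for property-based motif matching:
#' hydrophobic (A,V,L,I,M,F,W,Y), special (G,P,C), polar (S,T,N,Q),
#' positively charged (K,R,H), negatively charged (D,E). This grouping is a
#' package choice; any total map over the 20 standard residues may be
#' supplied instead.
#'
#' @return named character vector mapping each standard residue to a class
#'   label
#' @export
default_property_alphabet <- function() {
  classes <- list(
    hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y"),
    special     = c("G", "P", "C"),
    polar       = c("S", "T", "N", "Q"),
    positive    = c("K", "R", "H"),
    negative    = c("D", "E"))
  out <- character(0)
  for (cl in names(classes)) {
    v <- rep(cl, length(classes[[cl]]))
    names(v) <- classes[[cl]]
    out <- c(out, v)
  }
  out
}

check_alphabet <- function(alphabet) {
  missing <- setdiff(AA20, names(alphabet))
  if (length(missing) > 0)
    stop("property alphabet is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  alphabet
}

#' Property-class fuzzy motif scan
#'
#' Both the query and each window are mapped residue-wise through a
#' biochemical-property class map; the distance is the number of positions
#' whose class labels differ. Residue identity implies class identity, so
#' every exact hit is a property hit at distance 0. `X` has no class and
#' counts as a class mismatch; windows containing `*` are excluded.
#'
#' @inheritParams scan_exact
#' @param alphabet total map from residue to class label (default
#'   [default_property_alphabet()])
#' @param max_class_mismatches maximum number of class-differing positions
#'   (default 3)
#' @return data.frame of hits (see [scan_exact()])
#' @export
scan_property <- function(frames, query,
                          alphabet = default_property_alphabet(),
                          max_class_mismatches = 3L) {
  query <- check_query(query)
  alphabet <- check_alphabet(alphabet)
  if (max_class_mismatches < 0)
    stop("'max_class_mismatches' must be non-negative")
  dist_fun <- function(win, qchars) {
    qcl <- unname(alphabet[qchars])
    wcl <- matrix(alphabet[win], nrow = nrow(win))  # NA for 'X'/'*'
    mism <- (wcl != qcl) | is.na(wcl)
    colSums(mism)
  }
  scan_frames(frames, query, "property", as.integer(max_class_mismatches),
              dist_fun)
}

#' Keep the best hits per source sequence
#'
#' For each source id, retains the `per_source` best hits by ascending
#' distance, breaking ties by frame order (+1,+2,+3,-1,-2,-3) then window
#' offset.
#'
#' @param hits data.frame of hits as returned by the scan functions
#' @param per_source number of hits to keep per source (>= 1)
#' @return the filtered, sorted hit data.frame
#' @export
rank_candidates <- function(hits, per_source = 5L) {
  if (per_source < 1) stop("'per_source' must be >= 1")
  if (nrow(hits) == 0) return(hits)
  hits <- sort_hits(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$source), function(i) {
    ord <- order(hits$distance[i], frame_rank(hits$frame[i]),
                 hits$pep_offset[i])
    i[ord][seq_len(min(per_source, length(i)))]
  }), use.names = FALSE)
  sort_hits(hits[keep, , drop = FALSE])
}

#' Scan a FASTA file for a peptide motif
#'
#' Convenience driver: translates every record in six frames and runs the
#' requested scan mode.
#'
#' @param file FASTA path (or named character vector of sequences)
#' @param query peptide string (default the bundled HiBiT query)
#' @param mode one of `"exact"`, `"hamming"`, `"property"`
#' @param max_distance threshold for the fuzzy modes
#' @param top if non-NULL, keep only the best `top` hits per record
#' @param alphabet property class map for `mode = "property"`
#' @return data.frame of hits (see [scan_exact()])
#' @export
scan_fasta <- function(file, query = hibit_query(),
                       mode = c("hamming", "exact", "property"),
                       max_distance = 3L, top = NULL,
                       alphabet = default_property_alphabet()) {
  mode <- match.arg(mode)
  seqs <- if (is.character(file) && length(file) == 1 && file.exists(file))
    read_fasta(file) else file
  frames <- unlist(lapply(names(seqs), function(id)
    translate_six_frames(seqs[[id]], id)), recursive = FALSE)
  hits <- switch(mode,
    exact = scan_exact(frames, query),
    hamming = scan_hamming(frames, query, max_distance),
    property = scan_property(frames, query, alphabet, max_distance))
  if (!is.null(top)) hits <- rank_candidates(hits, top)
  hits
}

#' Construct a qPCR primer pair
#'
#' @param forward,reverse primer sequences, 5'->3', A/C/G/T only
#' @return `primer_pair` object
#' @export
primer_pair <- function(forward, reverse) {
  forward <- check_dna(forward, c("A", "C", "G", "T"), "forward primer")
  reverse <- check_dna(reverse, c("A", "C", "G", "T"), "reverse primer")
  structure(list(forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer pair>\n  fw:", x$forward, "\n  rv:", x$reverse, "\n")
  invisible(x)
}

find_all <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Predict a PCR product by exact primer matching
#'
#' Locates an exact full-length occurrence of one primer on the template's
#' forward strand and an exact occurrence of the other primer's reverse
#' complement downstream of it; the product spans from the 5' end of the
#' upstream match through the 3' end of the downstream match inclusive. Both
#' primer orientations are tried. If several products are possible the
#' shortest is returned and `multiple` is set.
#'
#' @param template DNA string (A/C/G/T)
#' @param primers a [primer_pair]
#' @param id template identifier recorded on the result
#' @param circular treat the template as circular by also scanning the
#'   junction (sequence concatenated with its first primer-length-1 bases)
#' @return `amplicon_prediction` object: `template`, `product` (logical),
#'   `start`/`end` (0-based half-open, forward strand), `length` (bp),
#'   `orientation` (which primer matched the forward strand), `multiple`
#' @export
insilico_pcr <- function(template, primers, id = "template",
                         circular = FALSE) {
  stopifnot(inherits(primers, "primer_pair"))
  template <- check_dna(template, c("A", "C", "G", "T"), "template")
  n <- nchar(template)
  ext <- max(nchar(primers$forward), nchar(primers$reverse)) - 1L
  subject <- if (circular) paste0(template, substr(template, 1L, ext))
             else template
  candidates <- list()
  for (orient in c("forward_on_plus", "reverse_on_plus")) {
    up <- if (orient == "forward_on_plus") primers$forward else primers$reverse
    dn <- if (orient == "forward_on_plus") primers$reverse else primers$forward
    up_pos <- find_all(up, subject)                # 1-based starts
    dn_pos <- find_all(revcomp(dn), subject)
    for (i in up_pos) {
      ends <- dn_pos[dn_pos >= i] + nchar(dn) - 1L # inclusive 1-based ends
      for (e in ends) {
        candidates[[length(candidates) + 1L]] <-
          list(start = i - 1L, end = e, length = e - i + 1L,
               orientation = orient)
      }
    }
  }
  if (length(candidates) == 0) {
    return(structure(list(template = id, product = FALSE, start = NA_integer_,
                          end = NA_integer_, length = NA_integer_,
                          orientation = NA_character_, multiple = FALSE),
                     class = "amplicon_prediction"))
  }
  lens <- vapply(candidates, `[[`, numeric(1), "length")
  best <- candidates[[which.min(lens)]]
  structure(list(template = id, product = TRUE,
                 start = as.integer(best$start), end = as.integer(best$end),
                 length = as.integer(best$length),
                 orientation = best$orientation,
                 multiple = length(candidates) > 1L),
            class = "amplicon_prediction")
}

#' @export
print.amplicon_prediction <- function(x, ...) {
  if (!x$product) {
    cat(sprintf("<in-silico PCR on %s> no product\n", x$template))
  } else {
    cat(sprintf("<in-silico PCR on %s> %d bp [%d, %d) %s%s\n",
                x$template, x$length, x$start, x$end, x$orientation,
                if (x$multiple) " (multiple products; shortest shown)" else ""))
  }
  invisible(x)
}

#' Average mass of a peptide
#'
#' Sum of standard average residue masses plus one water (18.02 Da).
#'
#' @param peptide amino-acid string, standard 20-letter alphabet, non-empty
#' @return mass in Da
#' @examples
#' peptide_average_mass("G")            # 75.07 Da
#' peptide_average_mass(hibit_query())  # ~1.3 kDa
#' @export
peptide_average_mass <- function(peptide) {
  peptide <- check_query(peptide)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  sum(AA_AVG_RESIDUE_MASS[chars]) + 18.02
}
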