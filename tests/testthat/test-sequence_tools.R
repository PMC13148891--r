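# Six-frame translation, motif scanning, in-silico PCR, peptide mass.

test_that("six-frame translation follows the genetic code on both strands", {
  fr <- translate_six_frames("ATGGCC", "x")
  expect_length(fr, 6)
  expect_equal(fr[[1]]$peptide, "MA")   # frame +1
  expect_equal(fr[[4]]$peptide, "GH")   # frame -1 = translation of GGCCAT
  expect_equal(vapply(fr, function(f) f$frame, integer(1)),
               c(1L, 2L, 3L, -1L, -2L, -3L))

  # hand-built codon-by-codon encoding of the HiBiT query (independent of
  # the package's reverse translation)
  codons <- c(V = "GTT", S = "TCT", G = "GGT", W = "TGG", R = "CGT",
              L = "CTT", F = "TTT", K = "AAA", I = "ATT")
  q <- strsplit("VSGWRLFKKIS", "")[[1]]
  seq33 <- paste(codons[q], collapse = "")
  expect_equal(nchar(seq33), 33)
  expect_equal(translate_six_frames(seq33, "q")[[1]]$peptide, "VSGWRLFKKIS")
})

test_that("translation marks stops and ambiguous codons and maps offsets", {
  fr <- translate_six_frames("ATGTAAANCGGG", "x")  # M * X G in frame +1
  expect_equal(fr[[1]]$peptide, "M*XG")
  expect_equal(fr[[1]]$nt_start, c(0L, 3L, 6L, 9L))
  # reverse-frame offset map round-trips through the reverse complement:
  # each mapped codon start must index a codon whose revcomp translates to
  # the reported residue
  s <- "GATTACAGGATCCA"
  f2 <- translate_six_frames(s, "x")[[5]]  # frame -2
  for (i in seq_len(nchar(f2$peptide))) {
    codon <- substr(s, f2$nt_start[i] + 1, f2$nt_start[i] + 3)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(codon, "")[[1]]),
                                       collapse = ""))
    expect_equal(unname(Biostrings::GENETIC_CODE[rc]),
                 substr(f2$peptide, i, i))
  }
})

test_that("translation rejects short and non-IUPAC input", {
  expect_error(translate_six_frames("AT"), "at least 3")
  expect_error(translate_six_frames("ATGQCC"), "position 4")
})

test_that("exact scan finds exactly the planted window", {
  g <- gen_plasmid_with_motif(frame = 2L, offset = 7L, length_nt = 300,
                              seed = 11)
  frames <- translate_six_frames(g$seq, g$id)
  hits <- scan_exact(frames, hibit_query())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$frame, 2L)
  expect_equal(hits$pep_offset, 7L)
  expect_equal(hits$distance, 0L)
  # agrees with the brute-force oracle at distance 0
  expect_equal(hit_core(hits),
               brute_scan(frames, hibit_query(), max_distance = 0))
})

test_that("query absent gives an empty result; two plants give two hits", {
  frames <- translate_six_frames(strrep("ACGT", 50), "bare")
  expect_equal(nrow(scan_exact(frames, hibit_query())), 0)

  set.seed(3)
  a <- gen_plasmid_with_motif(frame = 1L, offset = 2L, length_nt = 200)
  b <- gen_plasmid_with_motif(frame = -3L, offset = 4L, length_nt = 200)
  seq2 <- paste0(a$seq, b$seq)  # -3 plant lands in some reverse frame
  hits <- scan_exact(translate_six_frames(seq2, "double"), hibit_query())
  expect_equal(nrow(hits), 2)
  expect_equal(sort(sign(hits$frame)), c(-1, 1))
})

test_that("Hamming scan distances count mismatching positions", {
  g <- gen_plasmid_with_motif(frame = 1L, offset = 0L, n_mutations = 1L,
                              length_nt = 120, seed = 5)
  frames <- translate_six_frames(g$seq, g$id)
  hits <- scan_hamming(frames, hibit_query(), max_distance = 1)
  planted <- hits[hits$pep_offset == 0 & hits$frame == 1L, ]
  expect_equal(planted$distance, 1L)
  expect_equal(nrow(scan_exact(frames, hibit_query())[
    scan_exact(frames, hibit_query())$frame == 1L &
      scan_exact(frames, hibit_query())$pep_offset == 0, ]), 0)
  expect_error(scan_hamming(frames, hibit_query(), -1), "non-negative")
})

test_that("scanners match the brute-force oracle on random sequences", {
  set.seed(201)
  alpha <- default_property_alphabet()
  for (i in 1:6) {
    frames <- translate_six_frames(random_dna(sample(300:700, 1)),
                                   paste0("s", i))
    for (d in c(0L, 3L, 7L, 11L)) {
      expect_equal(hit_core(scan_hamming(frames, hibit_query(), d)),
                   brute_scan(frames, hibit_query(), "hamming", d))
      expect_equal(hit_core(scan_property(frames, hibit_query(), alpha, d)),
                   brute_scan(frames, hibit_query(), "property", d, alpha))
    }
    expect_equal(hit_core(scan_exact(frames, hibit_query())),
                 brute_scan(frames, hibit_query(), "hamming", 0))
  }
})

test_that("exact hits are contained in Hamming hits, and those in property hits", {
  set.seed(77)
  frames <- translate_six_frames(random_dna(900), "s")
  q <- hibit_query()
  key <- function(h) paste(h$frame, h$pep_offset)
  for (d in c(2L, 5L, 9L)) {
    ex <- scan_exact(frames, q)
    ham <- scan_hamming(frames, q, d)
    pro <- scan_property(frames, q, max_class_mismatches = d)
    expect_true(all(key(ex) %in% key(ham)))
    expect_true(all(key(ham) %in% key(pro)))
    # property distance never exceeds Hamming distance at matched windows
    m <- match(key(ham), key(pro))
    expect_true(all(pro$distance[m] <= ham$distance))
  }
})

test_that("reverse-complementing the input swaps +k and -k frame hits", {
  set.seed(99)
  s <- random_dna(600)
  n <- nchar(s)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  h1 <- scan_hamming(translate_six_frames(s, "s"), hibit_query(), 8)
  h2 <- scan_hamming(translate_six_frames(rc, "s"), hibit_query(), 8)
  expect_equal(nrow(h1), nrow(h2))
  # a hit at forward-strand codon start p maps to start n - p - 3 on the
  # reverse-complemented sequence, with the frame sign flipped
  k1 <- paste(h1$window, h1$distance, -sign(h1$frame), n - h1$nt_start - 3)
  k2 <- paste(h2$window, h2$distance, sign(h2$frame), h2$nt_start)
  expect_setequal(k1, k2)
})

test_that("property matching groups residues by class", {
  frames <- list(structure(list(source = "s", frame = 1L,
                                peptide = "ISGWRLFKKIS",
                                nt_start = 0:10 * 3L),
                           class = "frame_translation"))
  # V and I share the hydrophobic class: property distance 0, Hamming 1
  pro <- scan_property(frames, "VSGWRLFKKIS", max_class_mismatches = 0)
  expect_equal(pro$distance, 0L)
  ham <- scan_hamming(frames, "VSGWRLFKKIS", 11)
  expect_equal(ham$distance, 1L)
  # K -> D crosses charge classes: distance 1
  frames[[1]]$peptide <- "VSGWRLFDKIS"
  pro2 <- scan_property(frames, "VSGWRLFKKIS", max_class_mismatches = 11)
  expect_equal(pro2$distance, 1L)
  expect_error(scan_property(frames, "VSGWRLFKKIS",
                             alphabet = c(A = "x"), 0), "missing")
})

test_that("rank_candidates keeps best hits with deterministic tie-breaks", {
  h <- data.frame(source = "p", frame = c(1L, -2L, 3L),
                  pep_offset = c(0L, 1L, 2L), nt_start = c(0L, 10L, 20L),
                  window = "W", mode = "hamming", distance = c(3L, 5L, 2L),
                  stringsAsFactors = FALSE)
  top <- rank_candidates(h, 2)
  expect_equal(top$distance, c(2L, 3L))
  # equal distances order by frame (+1 before -2) then offset
  h$distance <- 4L
  top2 <- rank_candidates(h, 3)
  expect_equal(top2$frame, c(1L, 3L, -2L))
  expect_equal(nrow(rank_candidates(h[0, ], 2)), 0)
  expect_error(rank_candidates(h, 0), ">= 1")
})

test_that("in-silico PCR finds products, handles absence and multiplicity", {
  pp <- primer_pair("ATGCATGCAT", "GGGTTTCCCA")
  # minimal template: forward primer followed by revcomp(reverse)
  tmpl <- paste0(pp$forward, "TGGGAAACCC")
  amp <- insilico_pcr(tmpl, pp)
  expect_true(amp$product)
  expect_equal(amp$length, 20L)
  expect_equal(amp$length, amp$end - amp$start)
  # missing site -> explicit no-product result, not an error
  none <- insilico_pcr(strrep("AT", 30), pp)
  expect_false(none$product)
  expect_true(is.na(none$length))
  # two possible products -> shortest returned, multiplicity flagged
  tmpl2 <- paste0(pp$forward, "AAAA", "TGGGAAACCC", "CCCC", "TGGGAAACCC")
  amp2 <- insilico_pcr(tmpl2, pp)
  expect_true(amp2$multiple)
  expect_equal(amp2$length, 24L)
  expect_error(primer_pair("ATGN", "ACGT"), "position 4")
})

test_that("circular templates amplify across the origin when enabled", {
  pp <- primer_pair("ATGCATGCAT", "GGGTTTCCCA")
  # the reverse-primer site TGGGAAACCC straddles the origin: TGGG at the
  # template end, AAACCC at its start
  tmpl <- paste0("AAACCC", strrep("G", 20), pp$forward, "TGGG")
  expect_false(insilico_pcr(tmpl, pp)$product)
  amp <- insilico_pcr(tmpl, pp, circular = TRUE)
  expect_true(amp$product)
  expect_equal(amp$length, 20L)
})

test_that("peptide average mass is residue masses plus one water", {
  expect_equal(peptide_average_mass("G"), 75.07, tolerance = 1e-4)
  # additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(8)
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:5) {
    a <- paste(sample(aa, 4, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 6, replace = TRUE), collapse = "")
    expect_equal(peptide_average_mass(paste0(a, b)),
                 peptide_average_mass(a) + peptide_average_mass(b) - 18.02,
                 tolerance = 1e-9)
  }
  expect_error(peptide_average_mass(""), "non-empty")
  expect_error(peptide_average_mass("GB"), "position 2")
})

test_that("scan_fasta drives the scanners over multi-record files", {
  tf <- tempfile(fileext = ".fasta")
  set.seed(21)
  a <- gen_plasmid_with_motif(frame = 1L, offset = 3L, length_nt = 150,
                              id = "pA")
  b <- gen_plasmid_with_motif(frame = -1L, offset = 2L, length_nt = 150,
                              id = "pB")
  write_fasta(c(pA = a$seq, pB = b$seq), tf)
  hits <- scan_fasta(tf, mode = "exact")
  expect_setequal(hits$source, c("pA", "pB"))
  top <- scan_fasta(tf, mode = "hamming", max_distance = 11, top = 1)
  expect_equal(nrow(top), 2)
  expect_equal(top$distance, c(0L, 0L))
})
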