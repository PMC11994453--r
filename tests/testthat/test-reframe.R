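test_that("deletion filtering applies every criterion with an audit", {
  withr::with_seed(81, tc <- toy_deletion_case())
  v <- tc$variants
  extra <- tibble::tibble(
    chrom = c("chrT", "chrT", "chrT", "chrT"),
    pos = c(100L, 110L, 20L, 120L),
    ref = c("A", "ACT", substr(tc$chr_str, 20, 21), "CA"),
    alt = c("G", "A", substr(tc$chr_str, 20, 20), "C"),
    significance = c("Pathogenic", "Pathogenic", "Pathogenic", "Benign"))
  ## force the ref fields of the valid rows to match the genome
  extra$ref[4] <- substr(tc$chr_str, 120, 121)
  extra$alt[4] <- substr(tc$chr_str, 120, 120)
  vars <- dplyr::bind_rows(v, extra)
  res <- find_correctable_deletions(vars, tc$cds, tc$genome)
  expect_equal(nrow(res$deletions), 1L)            # only the planted one
  expect_equal(res$deletions$pos, v$pos)
  expect_equal(res$deletions$transcript, "tx1")
  ## audit accounts for every dropped record
  expect_equal(sum(res$audit$dropped), nrow(vars) - nrow(res$deletions))
  expect_gte(res$audit$dropped[res$audit$filter == "not_1nt_deletion"], 2L)
  expect_gte(res$audit$dropped[res$audit$filter == "not_pathogenic"], 1L)
  expect_gte(res$audit$dropped[res$audit$filter == "not_exonic"], 1L)
})

test_that("CDS validation errors name the offending transcript", {
  cds_bad <- tibble::tibble(transcript = "txX", chrom = "chrT",
                            strand = "+", start = 10L, end = 20L)
  expect_error(validate_cds(cds_bad), "txX")
})

test_that("guide placement honours the 0-4 nt PAM offset window", {
  ## deletion allele built explicitly, then the reference derived from it
  ## by re-inserting a base at the junction
  withr::with_seed(82, base <- rand_seq(121))
  base <- gsub("GG", "GA", base)
  base <- gsub("CC", "CA", base)                  # no stray PAMs
  allele <- base
  j <- 60L                                        # junction, 0-based
  ## plant NGG at offset 0 and offset 4 from the junction
  substr(allele, j + 1L, j + 3L) <- "TGG"         # PAM start q = j
  substr(allele, j + 5L + 1L, j + 5L + 2L) <- "AA"  # keep offsets 1-3 clean
  ref <- paste0(substr(allele, 1L, j), "T", substr(allele, j + 1L, nchar(allele)))
  dels <- tibble::tibble(chrom = "chrD", pos = j, ref = substr(ref, j, j + 1L),
                         alt = substr(ref, j, j), significance = "Pathogenic",
                         deleted_pos0 = j, transcript = "tx1")
  genome <- c(chrD = ref)
  plac <- place_guides(dels, genome)
  plus <- plac[plac$strand == "+", ]
  expect_true(0L %in% plus$pam_offset)
  expect_false(any(plus$pam_offset > 4L))
  expect_equal(plus$protospacer[plus$pam_offset == 0L],
               substr(allele, j - 19L, j))
  ## a PAM exactly 5 nt from the junction is not used: rebuild with the
  ## nearest PAM at offset 5 only
  allele5 <- base
  substr(allele5, j + 5L + 1L, j + 5L + 3L) <- "TGG"
  ref5 <- paste0(substr(allele5, 1L, j), "T",
                 substr(allele5, j + 1L, nchar(allele5)))
  plac5 <- place_guides(dplyr::mutate(dels, ref = substr(ref5, j, j + 1L),
                                      alt = substr(ref5, j, j)),
                        c(chrD = ref5))
  expect_false(any(plac5$strand == "+"))
  ## contig-end deletions are skipped with a warning
  edge <- dplyr::mutate(dels, deleted_pos0 = 5L, pos = 5L,
                        ref = substr(ref, 5, 6), alt = substr(ref, 5, 5))
  expect_warning(none <- place_guides(edge, genome), "contig end")
  expect_equal(nrow(none), 0L)
})

test_that("templated insertion outcomes match the translation oracle", {
  withr::with_seed(83, {
    n_checked <- 0L
    saw_restored <- FALSE
    saw_frame_only <- FALSE
    while (n_checked < 200L) {
      tc <- toy_deletion_case()
      res <- find_correctable_deletions(tc$variants, tc$cds, tc$genome)
      if (nrow(res$deletions) == 0L) next
      plac <- place_guides(res$deletions, tc$genome)
      if (nrow(plac) == 0L) next
      out <- templated_insertion_outcome(plac, tc$cds, tc$genome)

      ## independent oracle: per-base CDS mask, direct translation
      st0 <- oracle_state(tc$chr_str, tc$cds_start, tc$cds_end)
      prot_ref <- oracle_protein(st0, tc$cds$strand)
      st_del <- oracle_delete(st0, tc$del1)
      for (i in seq_len(nrow(out))) {
        cand <- out[i, ]
        ins_top <- if (cand$strand == "+") cand$insert_base
                   else chartr("ACGT", "TGCA", cand$insert_base)
        i0 <- if (cand$strand == "+") cand$allele_start + 17L
              else cand$allele_start + 3L
        st_ed <- oracle_insert(st_del, i0 + 1L, ins_top)
        frame_oracle <- (sum(st_ed$mask) %% 3L) == (sum(st0$mask) %% 3L)
        expect_identical(cand$frame_restored, frame_oracle)
        if (st_ed$inserted_in_cds) {
          prot_ed <- oracle_protein(st_ed, tc$cds$strand)
          prot_oracle <- frame_oracle && identical(prot_ed, prot_ref)
          expect_identical(cand$protein_restored, prot_oracle)
          if (isTRUE(prot_oracle)) saw_restored <- TRUE
          if (frame_oracle && !prot_oracle) saw_frame_only <- TRUE
        } else {
          expect_true(is.na(cand$protein_restored))
        }
        n_checked <- n_checked + 1L
      }
      ## protein recovery implies frame recovery, always
      expect_true(all(out$frame_restored[which(out$protein_restored)]))
    }
    ## both outcome types occurred, so the comparison is non-trivial
    expect_true(saw_restored)
    expect_true(saw_frame_only)
  })
})

test_that("an insertion reproducing the reference restores the protein", {
  ## guide placed so that position 17 duplicates the deleted base exactly
  withr::with_seed(84, {
    found <- FALSE
    for (try in 1:100) {
      tc <- toy_deletion_case()
      res <- find_correctable_deletions(tc$variants, tc$cds, tc$genome)
      if (nrow(res$deletions) == 0L) next
      plac <- place_guides(res$deletions, tc$genome)
      if (nrow(plac) == 0L) next
      out <- templated_insertion_outcome(plac, tc$cds, tc$genome)
      deleted_base <- substr(tc$chr_str, tc$del1, tc$del1)
      for (i in seq_len(nrow(out))) {
        cand <- out[i, ]
        ins_top <- if (cand$strand == "+") cand$insert_base
                   else chartr("ACGT", "TGCA", cand$insert_base)
        i0 <- if (cand$strand == "+") cand$allele_start + 17L
              else cand$allele_start + 3L
        ## the edit recreates the reference string exactly
        allele <- paste0(substr(tc$chr_str, 1, tc$del1 - 1L),
                         substr(tc$chr_str, tc$del1 + 1L, nchar(tc$chr_str)))
        edited <- paste0(substr(allele, 1, i0), ins_top,
                         substr(allele, i0 + 1L, nchar(allele)))
        if (identical(edited, tc$chr_str)) {
          expect_true(cand$protein_restored)
          expect_true(cand$frame_restored)
          found <- TRUE
        }
      }
      if (found) break
    }
    expect_true(found)
  })
})

test_that("candidates are ranked and classed by predicted blunt rate", {
  m_full <- fixture_model("full")
  m_red <- fixture_model("reduced")
  withr::with_seed(85, {
    protos <- vapply(1:40, function(.) rand_seq(20), "")
  })
  ## force a spread of predicted rates through the 17/18 context
  substr(protos[1:10], 17, 18) <- "GC"
  substr(protos[11:20], 17, 18) <- "TG"
  cand <- tibble::tibble(protospacer = protos)
  ranked <- rank_candidates(cand, list(spcas9 = m_full, alt = m_red))
  rc <- ranked$candidates
  expect_true(all(rc$class_spcas9[rc$rate_spcas9 > 0] == "blunt"))
  expect_true(all(rc$class_spcas9[rc$rate_spcas9 <= -2] == "highly_staggered"))
  expect_true(all(rc$class_spcas9[rc$rate_spcas9 <= 0 & rc$rate_spcas9 > -2]
                  == "staggered"))
  ## sorted by the first model's rate; extremes populated by construction
  expect_true(!is.unsorted(rc$rate_spcas9))
  expect_gte(sum(rc$class_spcas9 == "highly_staggered"), 5L)
  expect_gte(sum(rc$class_spcas9 == "blunt"), 5L)
  s <- ranked$summary
  expect_setequal(s$model, c("spcas9", "alt"))
  expect_true(all(s$n_exclusive <= s$n_highly_staggered))
  expect_lte(attr(s, "n_intersection"), min(s$n_highly_staggered))
})

test_that("T7 constructs carry the promoter, G start and scaffold", {
  out <- design_t7_construct("ATGCATGCATGCATGCATGC")
  expect_equal(nchar(out), 59L)
  expect_true(startsWith(out, "GGATCCTAATACGACTCACTATAG"))
  expect_true(endsWith(out, "GTTTTAGAGCTAGAA"))
  expect_equal(substr(out, 25, 25), "G")          # A start replaced by G
  g_spacer <- paste0("G", strrep("ACTT", 4), "CAT")
  expect_equal(substr(design_t7_construct(g_spacer), 25, 44), g_spacer)
  expect_error(design_t7_construct("NNGCATGCATGCATGCATGC"), "20-nt")
})
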