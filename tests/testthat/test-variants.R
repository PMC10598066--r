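# Funnel stages, impact classification, marker-offset estimation and the
# funnel's monotonicity/commutation properties.

test_that("impact classification reproduces the reported ICR assignments", {
  expect_equal(classify_impact("missense_variant"), "MODERATE")           # Apoc3, Nkx2-6, Gja8
  expect_equal(classify_impact("stop_lost"), "HIGH")                      # Phf11b
  expect_equal(classify_impact("disruptive_inframe_deletion"), "MODERATE") # RGD1305464
  expect_equal(classify_impact("conservative_inframe_insertion"), "MODERATE") # Sucla2
  # multi-term annotations take the most severe class
  expect_equal(classify_impact(c("splice_donor_variant", "splice_region_variant",
                                 "intron_variant")), "HIGH")              # Ppk
  expect_equal(classify_impact("splice_donor_variant&3_prime_UTR_variant&intron_variant"),
               "HIGH")                                                    # Srebf2
  expect_equal(classify_impact("synonymous_variant"), "LOW")
  expect_equal(classify_impact("made_up_term"), "UNCLASSIFIED")
  expect_equal(classify_impact(character()), "UNCLASSIFIED")
  # idempotent under severity-max combination and total over the vocabulary
  for (term in names(so_impact_table())) {
    single <- classify_impact(term)
    expect_false(single == "UNCLASSIFIED")
    expect_equal(classify_impact(c(term, term)), single)
  }
  # shipped table on all ICR records end-to-end
  v <- icr_reported_variants()
  expect_equal(setNames(v$impact, v$gene)[c("Apoc3", "Nkx2-6", "Gja8",
                                            "Phf11b", "RGD1305464",
                                            "Sucla2", "Ppk", "Srebf2")],
               c(Apoc3 = "MODERATE", `Nkx2-6` = "MODERATE", Gja8 = "MODERATE",
                 Phf11b = "HIGH", RGD1305464 = "MODERATE",
                 Sucla2 = "MODERATE", Ppk = "HIGH", Srebf2 = "HIGH"))
})

test_that("homozygosity and impact filters apply their pointwise rules", {
  v <- variant_records(rep("chr1", 4), 1:4, "A", "T",
                       genotype = c("hom_alt", "het", "hom_ref", "missing"),
                       so_terms = "missense_variant")
  expect_equal(filter_homozygous(v)$pos, 1)   # missing is not homozygous

  w <- variant_records(rep("chr1", 3), 1:3, "A", "T",
                       so_terms = c("missense_variant", "stop_lost",
                                    "synonymous_variant"))
  expect_equal(select_impact(w, c("MODERATE", "HIGH"))$pos, c(1, 2))
  expect_equal(nrow(select_impact(w, character())), 0L)
  # disjoint classes partition the selection
  expect_equal(nrow(select_impact(w, "MODERATE")) + nrow(select_impact(w, "HIGH")),
               nrow(select_impact(w, c("MODERATE", "HIGH"))))
})

test_that("cross-assembly concordance matches on gene/allele/effect, not coordinates", {
  a <- variant_records(c("chr1", "chr1"), c(100, 200), c("A", "C"), c("T", "G"),
                       gene = c("g1", "g2"),
                       so_terms = "missense_variant", assembly = "A")
  # same gene/allele/effect at shifted coordinates, g2 missing from B
  b <- variant_records("chr1", 90100, "A", "T", gene = "g1",
                       so_terms = "missense_variant", assembly = "B")
  conc <- cross_assembly_concordance(a, b, key = "gene")
  expect_equal(conc$gene, "g1")
  expect_equal(conc$pos, 100)  # assembly-A coordinates reported
  # coordinate mode requires exact positions
  expect_equal(nrow(cross_assembly_concordance(a, b, key = "coordinate")), 0L)
  expect_equal(nrow(cross_assembly_concordance(a, a, key = "coordinate")), 2L)
  # records without a gene symbol are excluded with a warning
  a2 <- a; a2$gene[1] <- ""
  expect_warning(out <- cross_assembly_concordance(a2, b, key = "gene"),
                 "gene symbol")
  expect_equal(nrow(out), 0L)
})

test_that("panel exclusion removes any-strain carriers and composes over panels", {
  case <- variant_records(c("chr15", "chr15"), c(37423413, 48760331),
                          c("A", "T"), c("T", "TGCA"),
                          gene = c("Fdft1", "Sucla2"),
                          so_terms = "missense_variant")
  panel <- icr_panel_stub()
  out <- panel_exclusion(case, panel)
  expect_equal(out$gene, "Sucla2")   # Fdft1 carried by a non-affected strain
  expect_equal(panel_exclusion(case, list()), case)  # empty panel: identity
  # a single carrier strain among many suffices (ANY-strain rule)
  many <- c(panel, list(empty1 = variant_records(character(), numeric(),
                                                 character(), character())))
  expect_equal(panel_exclusion(case, many)$gene, "Sucla2")
  # hom-only switch ignores het carriers
  het_panel <- list(s1 = variant_records("chr15", 37423413, "A", "T",
                                         genotype = "het"))
  expect_equal(nrow(panel_exclusion(case, het_panel, hom_only = TRUE)), 2L)
  expect_equal(nrow(panel_exclusion(case, het_panel, hom_only = FALSE)), 1L)
  # order-irrelevance: excluding against P1 then P2 equals P1 U P2
  set.seed(12)
  s <- random_variants(80); p1 <- random_variants(40); p2 <- random_variants(40)
  both <- panel_exclusion(s, list(p1, p2))
  seq_ <- panel_exclusion(panel_exclusion(s, list(p1)), list(p2))
  expect_equal(both, seq_)
})

test_that("locus restriction is inclusive at both ends and chromosome-aware", {
  thy_window <- locus_interval("Thy1_Cyp1a1", "chr8", 44393886, 58098974)
  v <- icr_reported_variants()
  inwin <- restrict_to_locus(v, thy_window)
  expect_true("Apoc3" %in% inwin$gene)     # chr8:46,532,966 inside
  expect_false("Gja8" %in% inwin$gene)     # chr2: chromosome mismatch
  edges <- variant_records(c("chr8", "chr8", "chr8"),
                           c(44393886, 58098974, 44393885), "A", "T")
  kept <- restrict_to_locus(edges, thy_window)
  expect_equal(kept$pos, c(44393886, 58098974))  # endpoints inclusive
  expect_error(locus_interval("x", "chr1", 10, 5), "start")
})

test_that("marker position estimation is exact under a uniform shift", {
  mk <- data.frame(
    name = c("anchor", "anchor", "m1", "m2"),
    assembly = c("src", "tgt", "src", "src"),
    chrom = "chr15",
    pos = c(1000, 5000, 400, 1700),
    stringsAsFactors = FALSE
  )
  # marker coincident with the anchor: estimate equals the anchor position
  mk0 <- rbind(mk, data.frame(name = "m0", assembly = "src",
                              chrom = "chr15", pos = 1000))
  expect_equal(estimate_marker_position(mk0, "m0", "anchor", "src", "tgt")$pos, 5000)
  # markers on both sides of the anchor under shift +4000: exact
  expect_equal(estimate_marker_position(mk, "m1", "anchor", "src", "tgt")$pos, 4400)
  expect_equal(estimate_marker_position(mk, "m2", "anchor", "src", "tgt")$pos, 5700)
  # random uniform shifts: estimates exact for all markers
  set.seed(30)
  for (i in 1:10) {
    shift <- sample(-1e5:1e5, 1)
    pos_src <- sort(sample.int(1e6, 5))
    tab <- rbind(
      data.frame(name = "A", assembly = "src", chrom = "c", pos = pos_src[1]),
      data.frame(name = "A", assembly = "tgt", chrom = "c", pos = pos_src[1] + shift),
      data.frame(name = paste0("m", 2:5), assembly = "src", chrom = "c",
                 pos = pos_src[2:5])
    )
    for (j in 2:5) {
      est <- estimate_marker_position(tab, paste0("m", j), "A", "src", "tgt")
      expect_equal(est$pos, pos_src[j] + shift)
    }
  }
  # chromosome mismatch is an error
  bad <- rbind(mk, data.frame(name = "mX", assembly = "src",
                              chrom = "chr16", pos = 10))
  expect_error(estimate_marker_position(bad, "mX", "anchor", "src", "tgt"),
               "chromosome")
})

test_that("the Cati2 interval start is reproduced from the inter-marker distance", {
  mk <- icr_marker_table()
  est <- estimate_marker_position(mk, "D15Rat52", "D15Rat20",
                                  source = "Rnor_6.0", target = "mRatBN7.2")
  # anchor at 52,813,021 minus the 20,135,471-base source distance
  expect_equal(est$pos, 52813021 - 20135471)
  expect_equal(est$pos, 32677550)
  expect_equal(est$chrom, "chr15")
})

test_that("the funnel kills each planted decoy at its designed stage", {
  spec <- variant_sim_spec(n_background = 100, n_decoys_per_mode = 4, seed = 6)
  sim <- simulate_variant_callsets(spec)
  fr <- run_variant_funnel(sim$case_a, sim$case_b, sim$panel,
                           loci = spec$causal_locus)
  expect_equal(nrow(fr$candidates), 1L)
  expect_equal(fr$candidates$gene, sim$causal$gene)

  truth <- sim$truth
  lookup <- function(v) paste(v$chrom, v$pos, sep = ":")
  tkey <- setNames(truth$class, paste(truth$chrom, truth$pos, sep = ":"))
  hom <- filter_homozygous(sim$case_a)
  expect_false(any(tkey[lookup(hom)] == "decoy_het"))
  sel <- select_impact(hom, c("MODERATE", "HIGH"))
  expect_false(any(tkey[lookup(sel)] == "decoy_low_impact"))
  conc <- cross_assembly_concordance(sel, select_impact(filter_homozygous(sim$case_b),
                                                        c("MODERATE", "HIGH")))
  expect_false(any(tkey[lookup(conc)] == "decoy_single_assembly_only"))
  excl <- panel_exclusion(conc, sim$panel)
  expect_false(any(tkey[lookup(excl)] == "decoy_panel_shared"))
  final <- restrict_to_locus(excl, spec$causal_locus)
  expect_false(any(tkey[lookup(final)] == "decoy_off_locus"))
  expect_equal(unname(tkey[lookup(final)]), "causal")
})

test_that("funnel edge cases: empty input and no-decoy spec", {
  spec <- variant_sim_spec(n_background = 0, n_decoys_per_mode = 0, seed = 1)
  sim <- simulate_variant_callsets(spec)
  fr <- run_variant_funnel(sim$case_a, sim$case_b, sim$panel,
                           loci = spec$causal_locus)
  # only the causal variant exists: every stage of its track passes 1
  expect_equal(nrow(fr$candidates), 1L)
  mod <- fr$stages[fr$stages$track %in% c("all", "MODERATE"), ]
  expect_true(all(mod$n_out <= mod$n_in))

  empty <- run_variant_funnel(sim$case_a[0, ], sim$case_b[0, ], sim$panel)
  expect_true(all(empty$stages$n_in == 0))
  expect_true(all(empty$stages$n_out == 0))
  expect_equal(nrow(empty$candidates), 0L)
})

test_that("homozygosity and locus restriction commute as pointwise predicates", {
  set.seed(44)
  locus <- locus_interval("L", "chr1", 2e5, 6e5)
  for (i in 1:30) {
    v <- random_variants(60)
    ab <- restrict_to_locus(filter_homozygous(v), locus)
    ba <- filter_homozygous(restrict_to_locus(v, locus))
    expect_equal(ab, ba)
  }
})
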