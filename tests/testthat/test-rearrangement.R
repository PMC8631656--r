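test_that("neighbourhood distances follow the end-to-start and start-to-start conventions", {
  g <- toy_genome()           # genes at 501..1000 (+) and 1423..2222 (+)
  nb <- extract_neighborhood(g, "OG2", k = 2L)
  expect_identical(nb$upstream$ortholog_id, "OG1")
  expect_identical(nb$intergenic_bp, 422L)          # 1423 - 1000 - 1
  expect_identical(nb$start_to_start_bp, 922L)      # 1423 - 501
  expect_identical(nrow(nb$downstream), 0L)
})

test_that("upstream is strand-aware: minus-strand focal looks at larger coordinates", {
  g <- toy_genome()
  g$genes$strand <- c("-", "-")
  g <- annotated_genome(g$strain_id, g$chromosomes, g$genes)
  nb <- extract_neighborhood(g, "OG1", k = 2L)      # focal now 501..1000 (-)
  expect_identical(nb$upstream$ortholog_id, "OG2")
  expect_identical(nb$intergenic_bp, 422L)
  nb2 <- extract_neighborhood(g, "OG2", k = 2L)     # first on its strand
  expect_identical(nrow(nb2$upstream), 0L)
  expect_true(is.na(nb2$intergenic_bp))
})

test_that("promoter classification compares nearest upstream orthologs", {
  tr <- make_translocation(seed = 101L, k = 8L)
  ref_nb <- extract_neighborhood(tr$reference, tr$focal)
  anc_nb <- extract_neighborhood(tr$reference, tr$focal)
  expect_identical(classify_promoter(anc_nb, ref_nb)$variant_class,
                   "ancestral")
  der_nb <- extract_neighborhood(tr$derived, tr$focal)
  cl <- classify_promoter(der_nb, ref_nb, tr$reference)
  expect_identical(cl$variant_class, "translocated")
  expect_identical(cl$partner_chromosome, "chrVII")
  expect_identical(cl$upstream_ortholog, tr$truth$upstream_ortholog)
  ## upstream ortholog unknown to the reference -> partner "unknown"
  der2 <- tr$derived
  der2$genes$ortholog_id[der2$genes$ortholog_id == cl$upstream_ortholog] <-
    "OG_alien"
  cl2 <- classify_promoter(extract_neighborhood(der2, tr$focal), ref_nb,
                           tr$reference)
  expect_identical(cl2$variant_class, "translocated")
  expect_identical(cl2$partner_chromosome, "unknown")
})

test_that("breakpoint localisation recovers planted junctions exactly at zero divergence", {
  for (k in c(0L, 8L)) {
    tr <- make_translocation(seed = 200L + k, k = k)
    fg <- ssuscan:::find_ortholog_gene(tr$derived, tr$focal)
    rec <- ssuscan:::upstream_window(tr$derived, fg, 5000L)
    bp <- locate_breakpoint(rec, tr$reference$chromosomes$chrXVI,
                            tr$reference$chromosomes$chrVII)
    expect_identical(bp$status, "resolved")
    expect_identical(bp$breakpoint_offset, 339L)
    expect_identical(bp$ambiguity_interval, c(339L, 339L + k))
    expect_identical(bp$microhomology_len, k)
    if (k > 0L) expect_identical(bp$microhomology_seq,
                                 tr$truth$microhomology_seq)
  }
})

test_that("a window identical to the ancestral chromosome yields no junction", {
  tr <- make_translocation(seed = 300L, k = 8L)
  fg <- ssuscan:::find_ortholog_gene(tr$reference, tr$focal)
  rec <- ssuscan:::upstream_window(tr$reference, fg, 5000L)
  ## parentB is an unrelated random sequence: no distal anchor exists
  unrelated <- withr::with_seed(1, ssuscan:::random_seq(20000L))
  bp <- locate_breakpoint(rec, tr$reference$chromosomes$chrXVI, unrelated)
  expect_identical(bp$status, "unresolved")
})

test_that("both reciprocal junctions carry the same microhomology and bases are conserved", {
  tr <- make_translocation(seed = 400L, k = 8L)
  count_bases <- function(g) {
    tab <- table(strsplit(paste(unlist(g$chromosomes), collapse = ""), "")[[1]])
    tab[order(names(tab))]
  }
  expect_identical(count_bases(tr$derived), count_bases(tr$reference))
  ## second junction: on the partner-derived chromosome, proximal side from
  ## the old partner chromosome, distal side from the old focal chromosome
  fg <- ssuscan:::find_ortholog_gene(tr$reference, tr$focal)
  cut_f <- fg$start - tr$truth$offset - 1L
  win2 <- substr(tr$derived$chromosomes$chrVII, cut_f - 2000L, cut_f + 3000L)
  bp2 <- locate_breakpoint(win2, tr$reference$chromosomes$chrVII,
                           tr$reference$chromosomes$chrXVI)
  expect_identical(bp2$status, "resolved")
  expect_identical(bp2$microhomology_seq, tr$truth$microhomology_seq)
})

test_that("motif retention follows the breakpoint geometry", {
  base <- withr::with_seed(5, ssuscan:::random_seq(1000L))
  plant_at <- function(w, dist, motif = "CTATCA") {
    # place the motif with its proximal edge `dist` bp upstream
    W <- nchar(w)
    substr(w, W - dist - nchar(motif) + 2L, W - dist + 1L) <- motif
    w
  }
  scrub <- gsub("CTATCA|TGATAG", "AAAAAA", base)
  expect_identical(motif_retention(scrub, "CTATCA")$motif_status, "absent")
  w <- plant_at(scrub, 500L)
  expect_identical(motif_retention(w, "CTATCA", 339L)$motif_status, "lost")
  w2 <- plant_at(scrub, 100L)
  expect_identical(motif_retention(w2, "CTATCA", 339L)$motif_status,
                   "retained")
  expect_identical(motif_retention(w, "CTATCA", NULL)$motif_status,
                   "retained")
  ## reverse-strand occurrence is found too
  w3 <- plant_at(scrub, 500L, motif = "TGATAG")
  res <- motif_retention(w3, "CTATCA", 339L)
  expect_identical(res$motif_status, "lost")
  expect_identical(min(res$positions), 500L)
})

test_that("scan_collection tabulates variant classes and flags uncallable strains", {
  tr <- make_translocation(seed = 500L, k = 8L)
  strains <- list(
    evolve_k81(tr$reference, 0.005, seed = 1L, strain_id = "a1"),
    evolve_k81(tr$reference, 0.005, seed = 2L, strain_id = "a2"),
    evolve_k81(tr$reference, 0.005, seed = 3L, strain_id = "a3"),
    evolve_k81(tr$derived, 0.005, seed = 4L, strain_id = "t1"),
    evolve_k81(tr$derived, 0.005, seed = 5L, strain_id = "t2"))
  ## a strain whose annotation lacks the focal ortholog is uncallable
  un <- strains[[1]]
  un$strain_id <- "u1"
  un$genes$ortholog_id[un$genes$ortholog_id == tr$focal] <- NA
  scan <- scan_collection(c(strains, list(un)), tr$reference, tr$focal)
  expect_identical(scan$calls$variant_class[scan$calls$strain == "u1"],
                   "uncallable")
  s <- scan$summary
  expect_identical(s$n[s$group == "ancestral"], 3L)
  expect_identical(s$n[s$group == "translocated:chrVII"], 2L)
  tcalls <- scan$calls[scan$calls$variant_class == "translocated", ]
  expect_true(all(tcalls$ambiguity_lo <= 339 & tcalls$ambiguity_hi >= 339))
})

test_that("calls are invariant to gene-table row order and to chromosome flips", {
  tr <- make_translocation(seed = 600L, k = 8L, divergence = 0.005)
  scan1 <- scan_collection(list(tr$derived), tr$reference, tr$focal)
  ## permute annotation rows (constructor re-sorts; readers sort too)
  shuf <- tr$derived
  perm <- withr::with_seed(1, sample(nrow(shuf$genes)))
  shuf <- annotated_genome(shuf$strain_id, shuf$chromosomes,
                           shuf$genes[perm, ])
  scan2 <- scan_collection(list(shuf), tr$reference, tr$focal)
  expect_identical(scan1$calls, scan2$calls)
  ## mirror the whole focal chromosome of the query strain
  flipped <- flip_chromosome(tr$derived, "chrXVI")
  scan3 <- scan_collection(list(flipped), tr$reference, tr$focal)
  cols <- c("variant_class", "partner_chromosome", "breakpoint_offset",
            "ambiguity_lo", "ambiguity_hi", "microhomology_len",
            "motif_status", "intergenic_bp", "start_to_start_bp")
  expect_identical(scan3$calls[, cols], scan1$calls[, cols])
})
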