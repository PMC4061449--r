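test_that("reads are gated on length and on retaining a passing hit", {
  h <- rbind(make_hits("r1", "A", read_length = 99),
             make_hits("r2", "A", read_length = 150, evalue = 1e-12),
             make_hits("r2", "B", read_length = 150, evalue = 1e-5),
             make_hits("r3", "A", read_length = 200, evalue = 1e-4))
  out <- filter_reads(h, min_length = 100, max_evalue = 1e-10)
  # r1 short, r3 has no passing hit; r2 keeps exactly its 1e-12 hit
  expect_equal(out$n_kept, 1)
  expect_equal(out$n_dropped, 2)
  expect_equal(out$hits$read_id, "r2")
  expect_equal(out$hits$species, "A")

  all_bad <- make_hits(c("r1", "r2"), "A", evalue = 1e-3)
  out2 <- filter_reads(all_bad)
  expect_equal(nrow(out2$hits), 0)
  expect_equal(out2$n_dropped, 2)
})

test_that("each read's unit vote is split 1/k over its distinct species", {
  h <- rbind(make_hits("r1", "A"), make_hits("r2", "B"),
             make_hits("r3", "A"), make_hits("r3", "B"))
  tl <- tally(h, clade_map = NULL)
  expect_equal(tl$votes[tl$species == "A"], 1.5)
  expect_equal(tl$votes[tl$species == "B"], 1.5)
  expect_equal(tl$percent, c(50, 50))

  # multiple hits to the same species count once per read
  dup <- rbind(make_hits("r1", "A"), make_hits("r1", "A"),
               make_hits("r1", "B"))
  td <- tally(dup, clade_map = NULL)
  expect_equal(sort(td$votes), c(0.5, 0.5))
})

test_that("near-indistinguishable species collapse to their clade name", {
  h <- rbind(make_hits("r1", "Bacillus thuringiensis"),
             make_hits("r2", "Bacillus anthracis"),
             make_hits("r3", "Shigella flexneri"),
             make_hits("r4", "Ralstonia pickettii"))
  tl <- tally(h)
  expect_setequal(tl$species,
                  c("Bacillus cereus", "Escherichia coli",
                    "Ralstonia pickettii"))
  expect_equal(tl$votes[tl$species == "Bacillus cereus"], 2)
})

test_that("votes are conserved through weighting and clade collapsing", {
  cfg <- sim_config(seed = 31,
                    composition = c("Bacillus thuringiensis" = 0.4,
                                    "Escherichia coli" = 0.35,
                                    "Ralstonia pickettii" = 0.25),
                    ambiguity_rate = 0.3)
  sim <- simulate_hits(cfg, 1e4)
  flt <- filter_reads(sim$hits)
  raw <- tally(flt$hits, clade_map = NULL)
  collapsed <- tally(flt$hits)
  n <- attr(raw, "n_reads_classified")
  expect_equal(sum(raw$votes), n, tolerance = 1e-6)
  expect_equal(sum(collapsed$votes), n, tolerance = 1e-6)
  # collapsing only repartitions mass
  expect_lte(nrow(collapsed), nrow(raw))
})

test_that("at zero ambiguity the tally equals the truth-label histogram", {
  cfg <- sim_config(seed = 32, composition = c(A = 0.6, B = 0.3, C = 0.1))
  sim <- simulate_hits(cfg, 5000)
  tl <- tally(sim$hits, clade_map = NULL)
  truth <- table(sim$reads$true_species)
  expect_equal(tl$votes[match(names(truth), tl$species)],
               as.numeric(truth))
})

test_that("simulated composition is recovered within 3 multinomial SDs", {
  cfg <- sim_config(seed = 33, composition = c(A = 0.7, B = 0.3))
  sim <- simulate_hits(cfg, 1e4)
  tl <- tally(sim$hits, clade_map = NULL)
  pA <- tl$percent[tl$species == "A"] / 100
  expect_lt(abs(pA - 0.7), 3 * sqrt(0.7 * 0.3 / 1e4))
})

test_that("sharing a read's hits across species down-weights the leader", {
  h <- rbind(make_hits(c("r1", "r2", "r3"), "A"), make_hits("r4", "B"))
  lead0 <- tally(h, clade_map = NULL)
  h_shared <- rbind(h, make_hits(unique(h$read_id), "Z"))
  lead1 <- tally(h_shared, clade_map = NULL)
  expect_lt(lead1$percent[lead1$species == "A"],
            lead0$percent[lead0$species == "A"])
})

test_that("score-proportional weighting still conserves the vote total", {
  h <- rbind(make_hits("r1", "A", bitscore = 300),
             make_hits("r1", "B", bitscore = 100),
             make_hits("r2", "B", bitscore = 250))
  tl <- tally(h, clade_map = NULL, weight_by = "score")
  expect_equal(sum(tl$votes), 2, tolerance = 1e-9)
  expect_equal(tl$votes[tl$species == "A"], 0.75)
})

test_that("relative sensitivity reproduces percentage-ratio arithmetic", {
  a <- taxon_tally(c("Bacillus cereus" = 99.5, other = 0.5))
  b <- taxon_tally(c("Bacillus cereus" = 0.02, other = 99.98))
  rs <- relative_sensitivity("Bacillus cereus", a, b, sig_figs = 2)
  expect_equal(rs$ratio, 5000)
  expect_false(rs$infinite)

  expect_equal(relative_sensitivity("Bacillus cereus", a, a)$ratio, 1)
  half <- taxon_tally(c(X = 50, Y = 50))
  quarter <- taxon_tally(c(X = 25, Y = 75))
  expect_equal(relative_sensitivity("X", half, quarter)$ratio, 2)

  zero <- taxon_tally(c(X = 0, Y = 10))
  expect_true(relative_sensitivity("X", half, zero)$infinite)
  expect_error(relative_sensitivity("missing", a, b), "absent")
})

test_that("tally refuses an empty hit table", {
  empty <- make_hits("r1", "A")[0, , drop = FALSE]
  expect_error(tally(empty), "no hits")
})
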