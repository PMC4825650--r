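test_that("all four filter thresholds are inclusive and jointly required", {
  at_threshold <- make_call(quality = 30, alt_frequency = 0.05, depth = 5,
                            prob_not_ref = 0.90)
  expect_equal(nrow(filter_calls(at_threshold)), 1)
  below_q <- make_call(quality = 29, alt_frequency = 0.5, depth = 10,
                       prob_not_ref = 0.95)
  expect_equal(nrow(filter_calls(below_q)), 0)
  ## each criterion alone can exclude
  for (tweak in list(list(quality = 29.9), list(alt_frequency = 0.049),
                     list(depth = 4), list(prob_not_ref = 0.899))) {
    call <- do.call(make_call, c(list(quality = 30, alt_frequency = 0.05,
                                      depth = 5, prob_not_ref = 0.90)[
                                        setdiff(c("quality", "alt_frequency",
                                                  "depth", "prob_not_ref"),
                                                names(tweak))], tweak))
    expect_equal(nrow(filter_calls(call)), 0)
  }
})

test_that("filtering an empty table returns an empty table and is idempotent", {
  empty <- make_call()[0, ]
  expect_equal(nrow(filter_calls(empty)), 0)
  set.seed(1)
  calls <- do.call(rbind, lapply(1:50, function(i)
    make_call(position = i, quality = runif(1, 10, 60),
              alt_frequency = runif(1), depth = sample(0:30, 1),
              prob_not_ref = runif(1))))
  once <- filter_calls(calls)
  expect_identical(filter_calls(once), once)
})

test_that("missing required fields are reported by record", {
  calls <- make_call()
  expect_error(filter_calls(calls[, setdiff(names(calls), "depth")]),
               "missing required field.*depth")
  calls2 <- rbind(make_call(position = 1), make_call(position = 2))
  calls2$quality[2] <- NA
  expect_error(filter_calls(calls2), "record 2 has missing 'quality'")
})

test_that("hemi flagging partitions on the open heterozygous band", {
  calls <- rbind(make_call(position = 1, alt_frequency = 0.50),
                 make_call(position = 2, alt_frequency = 1.00),
                 make_call(position = 3, alt_frequency = 0.20),
                 make_call(position = 4, alt_frequency = 0.80),
                 make_call(position = 5, alt_frequency = 0.21))
  parts <- flag_hemi_snps(calls)
  expect_equal(parts$hemi$position, c(1L, 5L))   # strictly inside (0.2, 0.8)
  expect_equal(parts$clean$position, c(2L, 3L, 4L))
  set.seed(2)
  rand <- do.call(rbind, lapply(1:80, function(i)
    make_call(position = i, alt_frequency = runif(1))))
  parts <- flag_hemi_snps(rand)
  expect_equal(nrow(parts$clean) + nrow(parts$hemi), nrow(rand))
})

test_that("hemi flagging recovers exactly the planted artifacts", {
  trio <- small_trio()
  filtered <- filter_calls(trio$calls1)
  parts <- flag_hemi_snps(filtered)
  truth <- trio$truth$hemi_positions
  truth1 <- truth[truth$parent == "parent1", ]
  expect_setequal(paste(parts$hemi$chromosome, parts$hemi$position),
                  paste(truth1$chromosome, truth1$position))
  planted <- trio$truth$planted_variants
  fixed1 <- planted[planted$parent %in% c("both", "parent1"), ]
  expect_false(any(paste(parts$hemi$chromosome, parts$hemi$position) %in%
                     paste(fixed1$chromosome, fixed1$position)))
})

test_that("three-list comparison follows the worked example", {
  a <- make_call(position = 10, ref = "A", alt = "G")
  b <- make_call(position = 20, ref = "C", alt = "T")
  p1 <- a
  p2 <- rbind(make_call(position = 10, ref = "A", alt = "G", parent = "parent2"),
              make_call(position = 20, ref = "C", alt = "T", parent = "parent2"))
  cmp <- compare_parents(p1, p2)
  expect_equal(cmp$shared_vs_reference$position, 10L)
  expect_equal(nrow(cmp$parent1_only), 0)
  expect_equal(cmp$parent2_only$position, 20L)
  expect_equal(cmp$polymorphic_between_parents$position, 20L)
  ## identical parents: nothing polymorphic
  cmp2 <- compare_parents(p2, p2)
  expect_equal(nrow(cmp2$polymorphic_between_parents), 0)
  expect_equal(nrow(cmp2$shared_vs_reference), 2)
})

test_that("conflicting reference alleles at one site are an error", {
  p1 <- make_call(position = 10, ref = "A", alt = "G")
  p2 <- make_call(position = 10, ref = "C", alt = "G", parent = "parent2")
  expect_error(compare_parents(p1, p2), "reference allele disagrees")
})

test_that("different alt alleles at one site give two polymorphic records", {
  p1 <- make_call(position = 10, ref = "A", alt = "G")
  p2 <- make_call(position = 10, ref = "A", alt = "T", parent = "parent2")
  cmp <- compare_parents(p1, p2)
  expect_equal(nrow(cmp$shared_vs_reference), 0)
  expect_equal(nrow(cmp$polymorphic_between_parents), 2)
})

test_that("comparison matches brute-force set algebra", {
  universe <- expand.grid(chromosome = c("A01", "C01"),
                          position = 1:25,
                          alt = c("G", "T"), stringsAsFactors = FALSE)
  set.seed(3)
  for (rep in 1:40) {
    n1 <- sample(0:10, 1); n2 <- sample(0:10, 1)
    i1 <- sample(nrow(universe), n1)
    i2 <- sample(nrow(universe), n2)
    mk <- function(idx, parent) {
      if (length(idx) == 0) return(make_call()[0, ])
      do.call(rbind, lapply(idx, function(j)
        make_call(chromosome = universe$chromosome[j],
                  position = universe$position[j],
                  ref = "A", alt = universe$alt[j], parent = parent)))
    }
    p1 <- mk(i1, "parent1"); p2 <- mk(i2, "parent2")
    cmp <- compare_parents(p1, p2)
    key <- function(d) sort(paste(d$chromosome, d$position, d$alt_allele))
    oracle <- oracle_compare_keys(
      paste(p1$chromosome, p1$position, p1$alt_allele),
      paste(p2$chromosome, p2$position, p2$alt_allele))
    expect_identical(key(cmp$shared_vs_reference), oracle$shared)
    expect_identical(key(cmp$parent1_only), oracle$p1_only)
    expect_identical(key(cmp$parent2_only), oracle$p2_only)
    expect_identical(key(cmp$polymorphic_between_parents), oracle$poly)
  }
})

test_that("accuracy estimation reproduces the manual-review arithmetic", {
  est <- estimate_accuracy(500, 414)
  expect_equal(est$percent, 82.8)
  expect_output(print(est), "82.8%", fixed = TRUE)
  expect_equal(estimate_accuracy(500, 500)$percent, 100)
  expect_equal(est$corrected_count(1e6), 828000)
  expect_error(estimate_accuracy(500, 501), "n_reviewed")
  expect_error(estimate_accuracy(0, 0), "> 0")
})
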