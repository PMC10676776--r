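test_that("initial populations are homopolymers of the requested base", {
  pop <- init_population(ga_config(pop_size = 5, init_length = 1000))
  expect_identical(nrow(pop), 5L)
  expect_true(all(pop$seq == strrep("A", 1000)))
  expect_true(all(is.na(pop$fitness)))
  expect_equal(gc_content(pop$seq), rep(0, 5))

  popg <- init_population(ga_config(pop_size = 3, init_base = "G"))
  expect_equal(gc_content(popg$seq), rep(1, 3))
  expect_error(ga_config(init_base = "N"), "init_base")
})

test_that("point mutation changes exactly one base, uniformly", {
  set.seed(71)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    m <- mutate_point(s)
    expect_identical(nchar(m), 30L)
    diff <- which(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
    expect_length(diff, 1L)
  }
  # replacement base uniform over the three alternatives (chi-square)
  set.seed(72)
  draws <- vapply(1:1500, function(i) mutate_point("A"), character(1))
  tab <- table(factor(draws, levels = c("C", "G", "T")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  set.seed(5); a <- mutate_point("ACGTACGT")
  set.seed(5); b <- mutate_point("ACGTACGT")
  expect_identical(a, b)
})

test_that("insertion and deletion shift length by one with full support", {
  set.seed(73)
  ins <- unique(vapply(1:300, function(i) mutate_insertion("AC"), character(1)))
  expect_true(all(nchar(ins) == 3L))
  support <- unlist(lapply(c("A", "C", "G", "T"), function(b)
    c(paste0(b, "AC"), paste0("A", b, "C"), paste0("AC", b))))
  expect_true(all(ins %in% support))

  dels <- unique(vapply(1:50, function(i) mutate_deletion("AC"), character(1)))
  expect_true(all(dels %in% c("A", "C")))

  s <- strrep("ACGT", 10)
  expect_identical(nchar(mutate_insertion(s)), nchar(s) + 1L)
  expect_identical(nchar(mutate_deletion(s)), nchar(s) - 1L)
})

test_that("structural variation reverses a segment, preserving composition", {
  # palindromic fixed point: homopolymer unchanged
  expect_identical(mutate_structural(strrep("A", 100), c(10, 20)),
                   strrep("A", 100))
  # full-sequence reversal
  set.seed(74)
  expect_identical(mutate_structural("AACCGG", c(6, 6)), "GGCCAA")
  # composition invariant, length invariant
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    m <- mutate_structural(s, c(50, 120))
    expect_identical(nchar(m), 200L)
    expect_identical(sort(strsplit(m, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  # shorter than the minimum segment: skipped
  expect_identical(mutate_structural("ACGT", c(50, 200)), "ACGT")
})

test_that("one generation: selection is stable under ties, size preserved", {
  cfg <- ga_config(pop_size = 10, init_length = 600,
                   length_bounds = c(500, 700), seed = 1)
  pop <- init_population(cfg)
  pop$seq <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = ""),
    character(1))
  const <- function(s) rep(0.7, length(s))
  set.seed(75)
  nxt <- step_generation(pop, const, cfg)
  expect_identical(nrow(nxt), 10L)
  # constant fitness: survivors are the first half by original index
  expect_identical(nxt$seq[1:5], pop$seq[1:5])
  expect_true(all(!is.na(nxt$fitness)))
})

test_that("evolution terminates, respects bounds and is reproducible", {
  # constant high fitness: terminates at the first evaluation (generation 0)
  r0 <- evolve(ga_config(pop_size = 6, seed = 2),
               function(s) rep(0.9, length(s)))
  expect_identical(r0$terminated_at, 0L)
  expect_true(r0$converged)
  expect_identical(nrow(r0$trajectory), 1L)

  # constant low fitness: runs exactly max_generations
  r1 <- evolve(ga_config(pop_size = 6, max_generations = 4, seed = 2),
               function(s) rep(0.1, length(s)))
  expect_identical(r1$terminated_at, 4L)
  expect_false(r1$converged)

  # a short GC-driven run: bounds, elitism monotonicity, reproducibility
  fit <- function(s) gc_content(s)
  cfg <- ga_config(pop_size = 20, init_length = 520,
                   length_bounds = c(500, 560), sv_segment_range = c(10, 50),
                   max_generations = 30, fitness_threshold = 0.2, seed = 6)
  r <- evolve(cfg, fit)
  lens <- nchar(r$population$seq)
  expect_true(all(lens >= 500 & lens <= 560))
  expect_true(all(diff(r$trajectory$max_fitness) >= -1e-12))
  r2 <- evolve(cfg, fit)
  expect_identical(r$population, r2$population)
  expect_identical(r$trajectory, r2$trajectory)
  expect_s3_class(autoplot(r), "ggplot")
  expect_identical(glance(r)$generations, r$terminated_at)
})

test_that("GC-target fitness recovers high-GC populations from all-A", {
  # reduced-size run: the population must climb until every individual
  # clears the fitness threshold (GC above ~0.425 for this toy objective)
  fit <- function(s) 1 - abs(gc_content(s) - 0.55) * 4
  cfg <- ga_config(pop_size = 40, init_length = 500,
                   length_bounds = c(400, 700), max_generations = 300,
                   seed = 8)
  r <- evolve(cfg, fit)
  expect_true(r$converged)
  expect_gt(min(r$population$fitness), 0.5)
  expect_gt(mean(gc_content(r$population$seq)), 0.42)
  # trajectory records the GC climb from 0
  expect_equal(r$trajectory$mean_gc[1], 0)
  expect_true(all(diff(r$trajectory$mean_gc) > -0.05))
})
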