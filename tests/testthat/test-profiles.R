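test_that("population scoring counts directions and forms the ratio", {
  probes <- sprintf("p%03d", 1:600)
  dirs <- rep("unchanged", 600)
  dirs[1:446] <- "increased"; dirs[447:454] <- "decreased"
  cc <- makeContrast(probes, dirs)
  sc <- scorePopulation(makeSet("dc", probes[1:454]), cc)
  expect_equal(sc$n1, 446); expect_equal(sc$n2, 8)
  expect_equal(sc$ratio, 446 / 8)                  # = 55.75
  sc2 <- scorePopulation(makeSet("even", probes[c(1:10, 447:454, 455:456)]),
                         cc)
  expect_equal(sc2$n1, 10); expect_equal(sc2$n2, 8)
  # absent probes excluded with a message
  expect_message(
    scorePopulation(makeSet("x", c(probes[1:3], "missing")), cc),
    "absent")
  sEq <- scorePopulation(makeSet("s", probes[1:20]),
                         makeContrast(probes[1:20],
                                      rep(c("increased", "decreased"), 10)))
  expect_equal(sEq$ratio, 1)
  expect_equal(sEq$pct_increased, 50)
})

test_that("ranking sorts by ratio with sentinel and tie rules", {
  sc <- data.frame(population_id = c("a", "b", "c", "d", "e", "f"),
                   ratio = c(5, Inf, 2, Inf, 3, NA),
                   n1 = c(10, 4, 8, 9, 30, 0))
  r <- rankPopulations(sc)
  expect_equal(r$population_id, c("d", "b", "a", "e", "c", "f"))
  # equal finite ratios: larger n1 first
  sc2 <- data.frame(population_id = c("x", "y"), ratio = c(3, 3),
                    n1 = c(12, 30))
  expect_equal(rankPopulations(sc2)$population_id, c("y", "x"))
  # agreement with a naive comparison sort over random score lists
  cmp <- function(i, j, s) {
    ri <- s$ratio[i]; rj <- s$ratio[j]
    if (is.na(ri) != is.na(rj)) return(is.na(rj))
    if (is.na(ri)) return(s$population_id[i] < s$population_id[j])
    if (ri != rj) return(ri > rj)
    if (s$n1[i] != s$n1[j]) return(s$n1[i] > s$n1[j])
    s$population_id[i] < s$population_id[j]
  }
  set.seed(37)
  for (rep in 1:10) {
    s <- data.frame(
      population_id = sprintf("p%02d", sample(99, 8)),
      ratio = sample(c(1, 2, 2, 5, Inf, Inf, NA, 0.5)),
      n1 = sample(0:20, 8, replace = TRUE))
    got <- rankPopulations(s)$population_id
    # insertion sort with the explicit comparator
    ord <- seq_len(8)
    for (i in 2:8) for (j in i:2)
      if (cmp(ord[j], ord[j - 1], s)) ord[c(j - 1, j)] <- ord[c(j, j - 1)]
    expect_equal(got, s$population_id[ord])
  }
})

test_that("redundancy filter removes only higher-ranked populations' probes", {
  hi <- makeSet("hi", c("a", "b", "c"))
  lo <- makeSet("lo", c("b", "c", "d"))
  sets <- list(hi = hi, lo = lo)
  expect_equal(filterUniqueSignatures(sets, c("hi", "lo"), "hi"),
               c("a", "b", "c"))                    # top rank untouched
  expect_equal(filterUniqueSignatures(sets, c("hi", "lo"), "lo"), "d")
  # pairwise disjoint sets: n_star = n everywhere
  d1 <- makeSet("d1", c("x", "y")); d2 <- makeSet("d2", c("z"))
  expect_length(filterUniqueSignatures(list(d1 = d1, d2 = d2),
                                       c("d1", "d2"), "d2"), 1L)
  expect_error(filterUniqueSignatures(sets, c("hi", "lo"), "zz"),
               "not in ranking")
})

test_that("buildProfile wires counts, both tests, and the joint flag", {
  probes <- sprintf("p%03d", 1:1000)
  dirs <- rep(c("increased", "decreased"), 500)   # 50% background
  dirs[1:100] <- "increased"
  cc <- makeContrast(probes, dirs)
  sets <- list(
    makeSet("invader", probes[1:100], class = "macrophage"),
    makeSet("decoy", probes[c(1:80, 101:120)], class = "monocyte"),
    makeSet("idle", probes[301:400], class = "T cell"))
  prof <- buildProfile(sets, cc, alpha = 0.05)
  r <- as.data.frame(profileRows(prof))
  expect_equal(r$population_id[1], "invader")
  inv <- r[r$population_id == "invader", ]
  expect_equal(inv$n_star, inv$n)                  # top rank keeps all
  expect_true(inv$significant)
  dec <- r[r$population_id == "decoy", ]
  expect_equal(dec$n_star, 20L)                    # shared 80 removed
  expect_true(dec$p1_adj < 0.05)                   # passes the raw test
  expect_false(dec$significant)                    # but not the filtered one
  # background from the same contrast over the full platform
  expect_equal(unname(profileBackground(prof)["m_total"]), 1000)
  expect_equal(unname(profileBackground(prof)["k_increased"]), 550)
  # profile invariant to the order populations are supplied in
  prof2 <- buildProfile(rev(sets), cc, alpha = 0.05)
  expect_equal(as.data.frame(profileRows(prof2)), r)
  # all-unchanged signatures: p1 = p2 = 1, flagged empty
  ccU <- makeContrast(probes, rep("unchanged", 1000))
  profU <- buildProfile(list(makeSet("u", probes[1:10])), ccU)
  rU <- as.data.frame(profileRows(profU))
  expect_equal(rU$p1_raw, 1); expect_equal(rU$p2_raw, 1)
  expect_true(rU$empty); expect_false(rU$significant)
})

test_that("duplicating a high-ranked population de-correlates the duplicate", {
  probes <- sprintf("p%03d", 1:1000)
  dirs <- rep(c("increased", "decreased"), 500)
  dirs[1:100] <- "increased"
  cc <- makeContrast(probes, dirs)
  orig <- makeSet("orig", probes[1:100])
  dup <- makeSet("orig2", probes[1:100])
  prof <- buildProfile(list(orig, dup), cc)
  r <- as.data.frame(profileRows(prof))
  second <- r[2, ]
  expect_equal(second$n_star, 0L)
  expect_equal(second$p2_raw, 1)
  expect_false(second$significant)
  expect_true(r$significant[1])
})

test_that("counts are conserved through the redundancy filter", {
  scen <- spikeScenario()
  r <- as.data.frame(profileRows(scen$profile))
  expect_true(all(r$n1_star + r$n2_star <= r$n1 + r$n2))
  expect_true(all(r$n1 + r$n2 <= r$n))
  noOverlap <- setdiff(r$population_id, c("pop01", "pop03"))
  expect_equal(r$n_star[r$population_id %in% noOverlap],
               r$n[r$population_id %in% noOverlap])
})

test_that("type-I error is controlled under a fair-coin null", {
  # directions assigned by fair coin against a 50% background; the joint
  # Hochberg-adjusted criterion should flag <= 5% of simulated families
  set.seed(41)
  nPop <- 20; nSig <- 60; reps <- 2000
  famErr <- 0
  m_total <- 10000; k_inc <- 5000
  for (rep in seq_len(reps)) {
    n1 <- rbinom(nPop, nSig, 0.5)
    p <- vapply(n1, function(x) hypergeomTail(x, nSig, k_inc, m_total),
                numeric(1))
    if (any(adjustHochberg(p) < 0.05)) famErr <- famErr + 1
  }
  expect_lte(famErr / reps, 0.05)
})

test_that("class summary takes the max ratio and any-significant flag", {
  scen <- spikeScenario()
  labels <- setNames(rep(c("myeloid", "lymphoid", "tissue"), length.out = 20),
                     sprintf("pop%02d", 1:20))
  cs <- classSummary(scen$profile, labels)
  r <- as.data.frame(profileRows(scen$profile))
  for (cl in cs$class_label) {
    member <- r[labels[r$population_id] == cl, ]
    expect_equal(cs$max_ratio[cs$class_label == cl],
                 max(member$ratio, na.rm = TRUE))
    expect_equal(cs$any_significant[cs$class_label == cl],
                 any(member$significant))
  }
  expect_error(classSummary(scen$profile, labels[-1]), "unmapped")
})

test_that("profiles serialize with the Inf convention", {
  probes <- sprintf("p%02d", 1:50)
  cc <- makeContrast(probes, rep(c("increased", "decreased"), 25))
  cc$direction[1:10] <- "increased"
  prof <- buildProfile(list(makeSet("a", probes[1:10])), cc)
  ft <- withr::local_tempfile(fileext = ".tsv")
  fj <- withr::local_tempfile(fileext = ".json")
  writeProfile(prof, ft); writeProfile(prof, fj)
  expect_true(any(grepl("\tInf\t", readLines(ft)))) # n2 = 0 sentinel as text
  tsv <- read.delim(ft)
  expect_identical(tsv$ratio, Inf)
  js <- jsonlite::read_json(fj)
  expect_true(js$rows[[1]]$infinite_ratio)
  expect_null(js$rows[[1]]$ratio)
  expect_equal(js$rows[[1]]$pct_increased, 100)
})
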