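## evidence builder: one junction with given per-(sample, method) entries
junction_ev <- function(start, entries) {
  data.table::rbindlist(lapply(entries, function(e)
    data.table::data.table(chrom = "1", start = as.integer(start),
                           end = as.integer(start + 500L), strand = "+",
                           sample_id = e[[1]], method = e[[2]],
                           read_count = as.integer(e[[3]]))))
}

test_that("default rule keeps >=2 methods AND >=2 reads, on planted cases", {
  ## A: 2 methods, max 3 reads -> kept; B: 1 method, 10 reads -> dropped;
  ## C: 2 methods, 1 read each -> dropped
  ev <- rbind(
    junction_ev(1000, list(list("s1", "ciri", 3), list("s1", "findcirc", 2))),
    junction_ev(3000, list(list("s1", "testrealign", 10))),
    junction_ev(5000, list(list("s1", "ciri", 1), list("s2", "findcirc", 1)))
  )
  rel <- select_reliable(ev, consensus_config())
  expect_equal(unique(rel$start), 1000L)
  expect_equal(circ_junctions(rel)$n_methods, 2L)
})

test_that("min_methods = min_reads = 1 is the identity filter", {
  ev <- random_evidence(25)
  rel <- select_reliable(ev, consensus_config(1L, 1L))
  expect_equal(as.data.frame(rel), as.data.frame(ev))
})

test_that("empty evidence selects nothing", {
  ev <- harmonize_calls(data.table::data.table())
  expect_equal(nrow(select_reliable(ev)), 0L)
})

test_that("min_methods exceeding enabled methods is a configuration error", {
  expect_error(consensus_config(3L, 2L, methods_enabled = c("ciri", "findcirc")),
               "exceeds")
  expect_error(consensus_config(0L), ">= 1")
})

test_that("selection matches a brute-force oracle over random instances", {
  set.seed(99)
  for (rep in 1:10) {
    ev <- random_evidence(30)
    for (mm in 1:3) for (mr in 1:3) {
      rel <- select_reliable(ev, consensus_config(mm, mr))
      got <- sort(unique(rel[, paste(chrom, start, end)]))
      expect_equal(got, sort(oracle_reliable_keys(ev, mm, mr)))
    }
  }
})

test_that("disabled methods contribute neither agreement nor support", {
  ev <- junction_ev(1000, list(list("s1", "ciri", 5), list("s1", "testrealign", 5)))
  cfg <- consensus_config(2L, 2L, methods_enabled = c("ciri", "findcirc"))
  expect_equal(nrow(select_reliable(ev, cfg)), 0L)
  cfg1 <- consensus_config(1L, 2L, methods_enabled = c("ciri", "findcirc"))
  rel <- select_reliable(ev, cfg1)
  expect_equal(unique(rel$method), "ciri")
})

test_that("per_sample scope requires method agreement within one sample", {
  ## two methods, but each in a different sample
  ev <- junction_ev(1000, list(list("s1", "ciri", 4), list("s2", "findcirc", 4)))
  expect_equal(nrow(select_reliable(ev, consensus_config(scope = "pooled"))), 2L)
  expect_equal(nrow(select_reliable(ev, consensus_config(scope = "per_sample"))), 0L)
  ev2 <- junction_ev(1000, list(list("s1", "ciri", 4), list("s1", "findcirc", 4)))
  expect_equal(nrow(select_reliable(ev2, consensus_config(scope = "per_sample"))), 2L)
})

test_that("support statistics reduce evidence as documented", {
  ev <- junction_ev(1000, list(list("s1", "ciri", 1), list("s1", "findcirc", 1),
                               list("s2", "ciri", 1)))
  ## max over entries = 1 < 2
  expect_equal(nrow(select_reliable(ev, consensus_config())), 0L)
  ## per-sample sum across methods: s1 has 1+1 = 2
  expect_equal(nrow(select_reliable(ev, consensus_config(
    support_statistic = "sum_over_methods"))), 3L)
  ## per-method sum across samples: ciri has 1+1 = 2
  expect_equal(nrow(select_reliable(ev, consensus_config(
    support_statistic = "sum_over_samples"))), 3L)
})

test_that("thresholds are monotone and reliable is always a subset of the union", {
  set.seed(7)
  for (rep in 1:10) {
    ev <- random_evidence(20)
    all_keys <- unique(ev[, paste(chrom, start, end)])
    prev <- NULL
    for (mm in 1:4) {
      rel <- select_reliable(ev, consensus_config(mm, 2L))
      keys <- unique(rel[, paste(chrom, start, end)])
      expect_true(all(keys %in% all_keys))
      if (!is.null(prev)) expect_true(all(keys %in% prev))
      prev <- keys
    }
    ## with min_methods = 4, every reliable junction has all four methods
    rel4 <- select_reliable(ev, consensus_config(4L, 1L))
    if (nrow(rel4))
      expect_true(all(circ_junctions(rel4)$n_methods == 4L))
  }
})

test_that("method agreement counts each circRNA once per method", {
  ev <- rbind(
    junction_ev(1000, list(list("s1", "ciri", 2), list("s2", "ciri", 3),
                           list("s1", "findcirc", 1), list("s1", "testrealign", 1),
                           list("s1", "circexplorer", 1))),
    junction_ev(3000, list(list("s1", "ciri", 2))),
    junction_ev(5000, list(list("s2", "findcirc", 9)))
  )
  agr <- method_agreement(ev)
  expect_equal(agr$n_union, 3L)
  expect_equal(unname(agr$per_method[c("ciri", "findcirc")]), c(2L, 2L))
  expect_equal(agr$histogram$n_circrnas[agr$histogram$n_methods == 1L], 2L)
  expect_equal(agr$histogram$n_circrnas[agr$histogram$n_methods == 4L], 1L)
  expect_equal(sum(agr$histogram$n_circrnas), agr$n_union)
})

test_that("agreement histogram equals an exhaustive set-intersection oracle", {
  set.seed(21)
  ev <- random_evidence(40)
  agr <- method_agreement(ev)
  keys <- unique(ev[, .(chrom, start, end)])
  nm <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- ev[chrom == keys$chrom[i] & start == keys$start[i] & end == keys$end[i]]
    nm[i] <- length(unique(sub$method))
  }
  oracle <- table(nm)
  for (k in names(oracle))
    expect_equal(agr$histogram[n_methods == as.integer(k), n_circrnas],
                 as.integer(oracle[[k]]))
  expect_equal(sum(agr$histogram$n_circrnas), agr$n_union)
})

test_that("per-sample counts tally union and reliable sets independently", {
  ev <- rbind(
    junction_ev(1000, list(list("s1", "ciri", 3), list("s1", "findcirc", 3))),
    junction_ev(3000, list(list("s1", "ciri", 9))),
    junction_ev(5000, list(list("s2", "testrealign", 4)))
  )
  rel <- select_reliable(ev)
  tab <- per_sample_counts(ev, rel)
  expect_equal(tab[sample_id == "s1", n_union], 2L)
  expect_equal(tab[sample_id == "s1", n_reliable], 1L)
  expect_equal(tab[sample_id == "s2", n_union], 1L)
  expect_equal(tab[sample_id == "s2", n_reliable], 0L)  # s2's junction not reliable
  expect_true(all(tab$n_reliable <= tab$n_union))
})
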