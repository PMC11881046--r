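# A small deterministic panel: affine predictors over the reference set,
# built from a full factorial grid so matched pairs are known exactly.
factorial_panel <- function() {
  grid <- expand.grid(
    qm_size = c("Min", "Int", "Big"), functional = c("TPSS", "B3LYP"),
    basis = c("SV(P)", "TZVPD"), dielectric = c("4", "20"),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  methods <- tibble::tibble(
    method_id = paste(grid$qm_size, grid$functional, grid$basis,
                      grid$dielectric, sep = "/"),
    engine = "qm_cluster", qm_size = grid$qm_size,
    functional = grid$functional, basis = grid$basis,
    dielectric = grid$dielectric, surroundings = "fixed", corrections = ""
  )
  ref <- bcp_reference()
  # deterministic slope per cell; B3LYP rows sit closer to slope 1 so the
  # functional comparison has a known winner in every matched pair
  b <- ifelse(grid$qm_size == "Min", 0.6,
              ifelse(grid$qm_size == "Int", 0.9, 1.8)) *
    ifelse(grid$functional == "B3LYP", 1.05, 0.92) *
    ifelse(grid$basis == "TZVPD", 0.97, 1)
  vals <- t(vapply(seq_len(nrow(grid)),
                   function(i) -0.8 + b[i] * ref$e_exp,
                   numeric(12)))
  list(methods = methods,
       table = potential_table(vals, methods = methods, sites = ref$abbr))
}

test_that("factor summaries aggregate min/mean/max per level", {
  panel <- factorial_panel()
  metrics <- metric_table(panel$table)
  fs <- summarize_by_factor(metrics, panel$methods, "qm_size")
  expect_setequal(unique(fs$level), c("Min", "Int", "Big"))
  expect_true(all(fs$min <= fs$mean + 1e-12 & fs$mean <= fs$max + 1e-12))
  # levels partition the panel
  sizes <- unique(fs[c("level", "n_methods")])
  expect_equal(sum(sizes$n_methods), nrow(panel$methods))

  # single method per level: min = mean = max
  m2 <- panel$methods[panel$methods$functional == "TPSS" &
                        panel$methods$basis == "SV(P)" &
                        panel$methods$dielectric == "4", ]
  met2 <- metrics[metrics$method_id %in% m2$method_id, ]
  fs2 <- summarize_by_factor(met2, m2, "qm_size")
  expect_equal(fs2$min, fs2$max)
  expect_equal(fs2$min, fs2$mean)

  # hand-computed level mean for one metric
  int_ids <- panel$methods$method_id[panel$methods$qm_size == "Int"]
  expect_equal(
    fs$mean[fs$level == "Int" & fs$metric == "madtr"],
    mean(metrics$madtr[metrics$method_id %in% int_ids])
  )
  expect_error(summarize_by_factor(metrics, panel$methods, "flavour"),
               "unknown factor")
})

test_that("matched-pair comparison enumerates exactly the single-factor pairs", {
  panel <- factorial_panel()
  metrics <- metric_table(panel$table)
  pc <- paired_comparison(metrics, panel$methods, "functional",
                          "B3LYP", "TPSS")
  # 3 sizes x 2 bases x 2 dielectrics matched cells
  expect_equal(pc$n_pairs, 12L)
  expect_equal(pc$wins_a + pc$wins_b + pc$ties, pc$n_pairs)

  # brute-force oracle over all method pairs
  ranks <- composite_rank(metrics)
  s <- ranks$avg6[match(panel$methods$method_id, ranks$method_id)]
  wins_a <- 0L; n <- 0L
  for (i in seq_len(nrow(panel$methods))) {
    for (j in seq_len(nrow(panel$methods))) {
      mi <- panel$methods[i, ]; mj <- panel$methods[j, ]
      if (mi$functional == "B3LYP" && mj$functional == "TPSS" &&
          mi$qm_size == mj$qm_size && mi$basis == mj$basis &&
          mi$dielectric == mj$dielectric) {
        n <- n + 1L
        if (s[i] < s[j]) wins_a <- wins_a + 1L
      }
    }
  }
  expect_equal(pc$n_pairs, n)
  expect_equal(pc$wins_a, wins_a)

  # swapping levels swaps the win counts
  pc_rev <- paired_comparison(metrics, panel$methods, "functional",
                              "TPSS", "B3LYP")
  expect_equal(pc_rev$wins_a, pc$wins_b)
  expect_equal(pc_rev$wins_b, pc$wins_a)

  # duplicated identical methods across levels tie everywhere
  dup_m <- panel$methods[c(1, 1), ]
  dup_m$functional <- c("TPSS", "B3LYP")
  dup_m$method_id <- c("d1", "d2")
  dup_metrics <- metrics[1:2, ]
  dup_metrics$method_id <- c("d1", "d2")
  dup_metrics[2, -1] <- dup_metrics[1, -1]
  pc_dup <- paired_comparison(dup_metrics, dup_m, "functional",
                              "TPSS", "B3LYP")
  expect_equal(pc_dup$ties, pc_dup$n_pairs)

  expect_warning(
    paired_comparison(metrics, panel$methods, "surroundings",
                      "fixed", "relaxed"),
    "no matched pairs"
  )
})

test_that("the study-shaped grid yields 24 matched pairs per two-level factor", {
  design <- synthetic_design()
  bench <- generate_benchmark(design, seed = 5)
  metrics <- metric_table(bench$table)
  # 24 Min + 12 Int + 12 Big QM-cluster methods
  expect_equal(as.vector(table(design$methods$qm_size)[c("Min", "Int", "Big")]),
               c(24L, 12L, 12L))
  pc_f <- paired_comparison(metrics, design$methods, "functional",
                            "B3LYP", "TPSS")
  expect_equal(pc_f$n_pairs, 24L)
  pc_b <- paired_comparison(metrics, design$methods, "basis",
                            "SV(P)", "TZVPD")
  expect_equal(pc_b$n_pairs, 24L)
})
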