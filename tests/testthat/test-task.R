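# Task construction: feature map, agent presets, feedback semantics, streams.

test_that("the feature map is the documented bijection", {
  fm <- animal_features()
  expect_equal(nrow(fm), 8)
  key <- paste(fm$size, fm$color, fm$species)
  expect_length(unique(key), 8) # bijection onto {size} x {color} x {species}
  expect_true(all(fm$class[fm$species == "wings"] == "bird"))
  expect_true(all(fm$class[fm$species == "gills"] == "fish"))
  st <- fm[fm$animal == "sturgeon", ]
  expect_equal(c(st$size, st$color, st$species), c("large", "gray", "gills"))
  ws <- fm[fm$animal == "whale_shark", ]
  expect_equal(c(ws$size, ws$color), c("large", "colorful"))
  pa <- fm[fm$animal == "parrot", ]
  expect_equal(c(pa$size, pa$color, pa$species), c("large", "colorful", "wings"))
})

test_that("feedback semantics are deterministic for every animal-report pair", {
  task <- concept_task("full_knowledge")
  gp <- build_generative_process(task)
  m <- build_agent_model(task)
  fm <- animal_features()
  for (animal in 1:8) {
    for (r in 1:11) {
      lv <- gp$feedback[animal, r]
      # exactly one feedback level has probability 1 in the agent's mapping
      p <- m$A[[4]][, animal, r]
      expect_equal(sort(p, decreasing = TRUE)[1], 1)
      expect_equal(which.max(p), lv)
      if (r == 1) expect_equal(lv, 1L)                       # null at start
      if (r >= 2 && r <= 9) {
        expect_equal(lv, if (r - 1 == animal) 3L else 4L)    # specific
      }
      if (r == 10) expect_equal(lv, if (fm$class[animal] == "bird") 2L else 4L)
      if (r == 11) expect_equal(lv, if (fm$class[animal] == "fish") 2L else 4L)
    }
  }
})

test_that("agent presets realize their knowledge structure", {
  full <- build_agent_model(concept_task("full_knowledge"))
  expect_null(full$a)
  expect_equal(full$B[[1]][, , 1], diag(8)) # concepts persist within a trial

  basic <- build_agent_model(concept_task("basic_only"))
  for (mod in 1:2) expect_true(all(basic$A[[mod]][, , 1] == 0.5))
  expect_true(all(basic$A[[3]][, , 1] %in% c(0, 1))) # species rows precise

  set.seed(9)
  slot5 <- build_agent_model(concept_task("slots", slots = 5L))
  col <- slot5$a[[1]][, 5, 1]
  expect_true(all(abs(col - 1) < 0.5))      # flat plus slight jitter
  expect_false(all(col == 1))               # jitter present
  known <- slot5$a[[1]][, 1, 1]
  expect_gt(max(known), 150)                # precise known column

  set.seed(9)
  gran <- build_agent_model(concept_task("granularity", prior_basic = TRUE))
  expect_lt(max(gran$a[[1]]), 2)            # size rows naive
  expect_gt(max(gran$a[[3]]), 150)          # species rows precise
})

test_that("the basic-only agent never reports specific categories", {
  m <- build_agent_model(concept_task("basic_only"))
  gp <- build_generative_process(m$task)
  pr <- freeze_and_probe(m, gp, probes_per_animal = 4)
  expect_equal(pr$generic_accuracy, 1)
  expect_equal(pr$prop_specific, 0)
})

test_that("the distance-question variant generalizes one-shot", {
  g <- build_generalization_task("parrot")
  expect_equal(dim(g$model$A[[4]]), c(3, 8, 3))
  expect_equal(g$gp$labels$reports, c("start", "yes", "no"))
  # all-known control answers from its concept knowledge: whale shark -> yes
  ctrl <- exp_generalization("none", probes = 1, seed = 1)
  expect_equal(ctrl$per_repeat$accuracy, 1)
  # withheld yes-case and no-case animals (scaled probes; the acceptance
  # suite runs the full 20)
  expect_equal(exp_generalization("parrot", probes = 5)$per_repeat$accuracy, 1)
  expect_equal(exp_generalization("minnow", probes = 5)$per_repeat$accuracy, 1)
})

test_that("stimulus streams honor their schedules and seeds", {
  bal <- sample_stimulus_stream(c(1, 5, 2, 7, 4), per_animal = 250,
                                kind = "balanced", seed = 3)
  expect_equal(as.numeric(table(bal)), rep(250, 5))
  expect_length(bal, 1250)

  uni <- sample_stimulus_stream(1:8, n = 2000, kind = "uniform", seed = 3)
  counts <- table(factor(uni, levels = 1:8))
  # every count inside the binomial 99% interval around 250
  ci <- qbinom(c(0.005, 0.995), 2000, 1 / 8)
  expect_true(all(counts >= ci[1] & counts <= ci[2]))

  expect_identical(uni, sample_stimulus_stream(1:8, n = 2000,
                                               kind = "uniform", seed = 3))
})
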