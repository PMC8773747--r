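test_that("hemisphere amplitude is the absolute maximum over the channel set", {
  t_rel <- seq(-1, 60, by = 0.5)
  ga <- matrix(0, 15, length(t_rel))
  expect_equal(hemisphere_amplitude(ga, 1:7, t_rel), 0)
  ga[3, 40] <- -3
  ga[3, 50] <- 1
  expect_equal(hemisphere_amplitude(ga, 3, t_rel), 3)
  ga[5, 60] <- 5
  # brute force over the set: max of per-channel absolute maxima
  brute <- max(apply(abs(ga[c(3, 5), t_rel >= 0]), 1, max))
  expect_equal(hemisphere_amplitude(ga, c(3, 5), t_rel), brute)
  expect_equal(hemisphere_amplitude(ga, c(3, 5), t_rel, mode = "mean"),
               mean(c(3, 5)))
  expect_error(hemisphere_amplitude(ga, integer(0), t_rel), "non-empty",
               class = "nirslat_validation_error")
})

test_that("amplitudes outside the task interval are ignored", {
  t_rel <- seq(-1, 60, by = 0.5)
  ga <- matrix(0, 15, length(t_rel))
  ga[1, 1] <- 100  # at t = -1 s, before the onset
  ga[1, 10] <- 2
  expect_equal(hemisphere_amplitude(ga, 1, t_rel, interval = c(0, 60)), 2)
})

test_that("the laterality index matches its closed form and conventions", {
  expect_equal(compute_lis(1, 1), 0)
  expect_equal(compute_lis(1, 0), 1)
  expect_equal(compute_lis(0, 1), -1)
  expect_equal(compute_lis(3, 1), 0.5)
  expect_error(compute_lis(0, 0), class = "nirslat_undefined_laterality")
  expect_error(compute_lis(-1, 1), class = "nirslat_validation_error")
})

test_that("group laterality is zero for symmetric cohorts and follows gains", {
  sched <- build_session_schedule(1, 0)
  sym <- lapply(c("control", "eustress", "distress"), function(g)
    epoch_entry(g, 1, preprocessed_epochs(sched, gain = 1)))
  tab <- lis_by_group_session(sym)
  expect_equal(tab$lis, rep(0, 3))
  expect_equal(tab$R, tab$L)

  # eustress gain 2, others 1: closed form (2-1)/(2+1)
  mixed <- list(
    epoch_entry("control", 1, preprocessed_epochs(sched, gain = 1)),
    epoch_entry("eustress", 1, preprocessed_epochs(sched, gain = 2)),
    epoch_entry("distress", 1, preprocessed_epochs(sched, gain = 1)))
  tab2 <- lis_by_group_session(mixed)
  expect_equal(tab2$lis[tab2$group == "eustress"], 1 / 3, tolerance = 1e-9)
  expect_equal(tab2$lis[tab2$group != "eustress"], c(0, 0))
})

test_that("laterality is invariant to the overall response scale", {
  sched <- build_session_schedule(1, 0)
  small <- preprocessed_epochs(sched, gain = 1.4,
                               params = noiseless_params(amplitude = 1))
  large <- preprocessed_epochs(sched, gain = 1.4,
                               params = noiseless_params(amplitude = 37.5))
  t1 <- lis_by_group_session(list(epoch_entry("control", 1, small)))
  t2 <- lis_by_group_session(list(epoch_entry("control", 1, large)))
  expect_equal(t1$lis, t2$lis, tolerance = 1e-12)
})

test_that("laterality increases monotonically with the right-hemisphere gain", {
  sched <- build_session_schedule(1, 0)
  gains <- c(1, 1.2, 1.5, 2, 3)
  lis <- vapply(gains, function(g) {
    tab <- lis_by_group_session(list(
      epoch_entry("g", 1, preprocessed_epochs(sched, gain = g))))
    tab$lis
  }, numeric(1))
  expect_true(all(diff(lis) > 0))
  expect_equal(lis, (gains - 1) / (gains + 1), tolerance = 1e-9)
})

test_that("the midline channel never enters the hemisphere amplitudes", {
  sched <- build_session_schedule(1, 0)
  ep <- preprocessed_epochs(sched, gain = 1)
  ep$hbo[, 8, ] <- ep$hbo[, 8, ] + 50  # corrupt only the midline channel
  tab <- lis_by_group_session(list(epoch_entry("control", 1, ep)))
  expect_equal(tab$lis, 0)
})

test_that("empty groups are rejected and the table layout is complete", {
  sched <- build_session_schedule(1, 0)
  entry <- epoch_entry("control", 1, preprocessed_epochs(sched, gain = 1))
  tab <- lis_by_group_session(list(entry))
  expect_named(tab, c("group", "session", "R", "L", "lis", "lis_se", "n",
                      "aggregation_mode"))
  expect_error(lis_by_group_session(list()), "empty",
               class = "nirslat_validation_error")
})

test_that("laterality tables can be compared against reference values", {
  tab <- data.frame(group = c("a", "b"), session = 1, lis = c(0.11, 0.50))
  ref <- data.frame(group = c("a", "b"), session = 1, lis = c(0.12, 0.30))
  cmp <- compare_lis_tables(tab, ref, tol = 0.02)
  expect_equal(cmp$agree, c(TRUE, FALSE))
  expect_equal(cmp$delta, c(-0.01, 0.20), tolerance = 1e-12)
})
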