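test_that("the assembled network has the prescribed structure", {
  net <- build_network("16deg", cached_config())
  ids <- names(net$neurons)
  expect_length(ids, 15L)                       # one OPN, 7 pairs
  expect_equal(sum(ids == "OPN"), 1L)
  expect_false(any(net$connections$source == net$connections$target))
  need <- rbind(
    c("LLBN_i", "OPN", -1), c("LLBN_i", "IBN_i", +1),
    c("OPN", "EBN_i", -1), c("OPN", "IBN_i", -1),
    c("OPN", "EBN_c", -1), c("OPN", "IBN_c", -1),
    c("IBN_i", "EBN_c", -1), c("IBN_i", "TN_c", -1),
    c("IBN_i", "AN_c", -1), c("IBN_i", "ON_i", -1),
    c("IBN_i", "IN_i", -1), c("EBN_i", "TN_i", +1),
    c("EBN_i", "AN_i", +1), c("TN_i", "IN_i", +1),
    c("IN_i", "AN_i", +1), c("AN_i", "ON_c", +1))
  key <- paste(net$connections$source, net$connections$target,
               net$connections$sign)
  expect_true(all(paste(need[, 1], need[, 2], need[, 3]) %in% key))
  # mirrored wiring for the other side
  expect_true(all(c("LLBN_c OPN -1", "AN_c ON_i 1") %in% key))
  expect_error(build_network("33deg", cached_config()),
               "unknown scenario")
})

test_that("rate extraction is the reciprocal interspike interval", {
  tt <- seq(0, 50, by = 0.1)
  expect_equal(extract_rate_signal(numeric(), tt), rep(0, length(tt)))
  r <- extract_rate_signal(seq(5, 25, by = 1), tt)
  expect_equal(unique(r[tt > 5.1 & tt < 24.9]), 1000)
  expect_true(all(r[tt < 4.9] == 0) && all(r[tt > 25.1] == 0))
  # two-rate train: 2 ms then 5 ms intervals
  sp <- c(seq(0, 10, by = 2), seq(15, 40, by = 5))
  r2 <- extract_rate_signal(sp, tt)
  expect_equal(unique(r2[tt > 0.1 & tt < 9.9]), 500)
  expect_equal(unique(r2[tt > 15.1 & tt < 39.9]), 200)
})

test_that("the omnipause gate and the burster are mutually exclusive", {
  r <- cached_run("16deg")
  sp <- r$sim$spikes
  ebn <- sp$EBN_i[sp$EBN_i > r$times$t1 - 10 &
                    sp$EBN_i < r$times$t_end - 10]
  expect_gt(length(ebn), 20)
  opn_inside <- sp$OPN[sp$OPN > min(ebn) - 1 & sp$OPN < max(ebn) + 1]
  expect_length(opn_inside, 0)
})

test_that("an unperturbed omnipause neuron keeps the burster silent", {
  cfg <- cached_config()
  net <- build_network("16deg", cfg)
  # remove the collicular/cerebellar drives: the OPN is never inhibited
  for (id in c("LLBN_i", "EBN_i", "IBN_i", "EBN_c", "IBN_c"))
    net$drives[[id]] <- NULL
  sim <- simulate_circuit(net, duration = 250, config = cfg)
  expect_length(sim$spikes$EBN_i, 0)
  expect_length(sim$spikes$EBN_c, 0)
  expect_gt(length(sim$spikes$OPN), 20)   # OPN stays tonic throughout
})

test_that("the burster shows no rebound burst after the saccade", {
  for (sc in c("4deg", "16deg", "20deg")) {
    r <- cached_run(sc)
    late <- r$sim$spikes$EBN_i[r$sim$spikes$EBN_i > r$times$t_end + 15]
    expect_length(late, 0)
  }
})

test_that("identical configurations give bit-identical spike trains", {
  cfg <- cached_config()
  net <- build_network("8deg", cfg)
  s1 <- simulate_circuit(net, config = cfg)
  s2 <- simulate_circuit(net, config = cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$V_axon, s2$V_axon)
})

test_that("the motoneuron peak rate does not encode saccade magnitude", {
  peaks <- vapply(all_scenarios, function(sc) {
    r <- cached_run(sc)
    sp <- r$sim$spikes$AN_i
    sp <- sp[sp > r$times$t1 - 10 & sp < r$times$t_end]
    1000 / min(diff(sp))
  }, numeric(1))
  expect_lt((max(peaks) - min(peaks)) / mean(peaks), 0.10)
})

test_that("contralateral commands mirror the ipsilateral ones", {
  r <- cached_run("16deg")
  cfg <- cached_config()
  ci <- r$commands
  cc_ <- motoneuron_commands(r$sim, "c", cfg)
  # both eyes' agonists are driven to the same pulse and step
  expect_equal(max(cc_$N_ag), max(ci$N_ag), tolerance = 0.05)
  late <- r$time > r$times$t_end + 100
  expect_equal(mean(cc_$N_ag[late]), mean(ci$N_ag[late]),
               tolerance = 0.02)
  # and the burst windows overlap substantially
  wi <- range(r$time[ci$N_ag == max(ci$N_ag)])
  wc <- range(r$time[cc_$N_ag == max(cc_$N_ag)])
  expect_lt(abs(wi[1] - wc[1]), 6)
  expect_lt(abs(wi[2] - wc[2]), 6)
})

test_that("burst onsets follow the physiological firing order", {
  # relative to the nominal saccade anchors, for every scenario
  for (sc in all_scenarios) {
    ch <- choreography(cached_run(sc))
    expect_lt(abs(ch$LLBN_on - (-20)), 2)
    expect_true(ch$OPN_pause_on >= -12 && ch$OPN_pause_on <= -4)
    expect_true(ch$EBN_on >= -10 && ch$EBN_on <= -4)
    expect_true(ch$IBN_on >= -10 && ch$IBN_on <= -4)
    # the cascade is ordered: LLBN, then the pause, then the bursters
    expect_lt(ch$LLBN_on, ch$OPN_pause_on)
    expect_lte(ch$OPN_pause_on, ch$EBN_on)
  }
})

test_that("burst offsets land in the model's termination windows", {
  for (sc in all_scenarios) {
    r <- cached_run(sc)
    ch <- choreography(r)
    sp <- r$sim$spikes
    an_on <- min(sp$AN_i[sp$AN_i >= ch$EBN_on + ch$t1]) - ch$t1
    an_off <- max(sp$AN_i[sp$AN_i < ch$t_end]) - ch$t_end
    expect_true(ch$EBN_off >= -10.5 && ch$EBN_off <= -3)
    expect_true(ch$IBN_off >= -14 && ch$IBN_off <= -8)
    expect_true(an_on >= -7 && an_on <= -3)
    expect_true(an_off >= -8.5 && an_off <= 0.5)
    expect_lt(abs(ch$LLBN_off), 5)       # ends almost with the saccade
    expect_lt(abs(ch$OPN_resume), 5)     # pause ends almost with it too
    # the tonic interneuron is silenced in the pulse and resumes by the end
    insac <- sp$IN_i[sp$IN_i > ch$t1 & sp$IN_i < ch$t_end - 15]
    expect_lte(length(insac), 3)
    expect_lt(min(sp$IN_i[sp$IN_i > ch$t_end - 15]) - ch$t_end, 5)
  }
})
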