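test_that("advance_state applies rules, schedules, and clamps", {
  net <- terminal_network()
  s0 <- c(Cad = 0L, D = 0L, Opa = 0L, Fkh = 0L, Wg = 0L,
          Tll = 0L, Hkb = 0L)
  nxt <- advance_state(net, s0, inputs = c(Tll = 0L, Hkb = 0L))
  # From an all-off state with no terminal input: Cad default-on, weak
  # basal D, the Opa ratchet takes its first step.
  expect_identical(nxt[["Cad"]], 1L)
  expect_identical(nxt[["D"]], 1L)
  expect_identical(nxt[["Opa"]], 1L)
  expect_identical(nxt[["Fkh"]], 0L)
  expect_identical(nxt[["Wg"]], 0L)

  # Trunk mid-blastoderm state: D represses Cad, Cad keeps D strong,
  # Opa ratchets to strong.
  s1 <- c(Cad = 1L, D = 2L, Opa = 1L, Fkh = 0L, Wg = 0L,
          Tll = 0L, Hkb = 0L)
  nxt1 <- advance_state(net, s1, inputs = c(Tll = 0L, Hkb = 0L))
  expect_identical(unname(nxt1[c("Cad", "D", "Opa")]), c(0L, 2L, 2L))

  # Clamps win over rules and schedules at every step.
  nxt_ko <- advance_state(net, s1, inputs = c(Tll = 2L, Hkb = 0L),
                          genotype = "tll-")
  expect_identical(nxt_ko[["Tll"]], 0L)
  nxt_cad <- advance_state(net, s0, inputs = c(Tll = 0L, Hkb = 0L),
                           genotype = "cad-")
  expect_identical(nxt_cad[["Cad"]], 0L)

  # Scheduled inputs propagate verbatim.
  expect_identical(advance_state(net, s0,
                                 c(Tll = 2L, Hkb = 1L))[["Tll"]], 2L)
})

test_that("advance_state errors name the missing factor", {
  net <- terminal_network()
  s_bad <- c(Cad = 0L, D = 0L, Opa = 0L, Fkh = 0L, Wg = 0L, Tll = 0L)
  expect_error(advance_state(net, s_bad, c(Tll = 0L, Hkb = 0L)), "Hkb")
  s0 <- c(s_bad, Hkb = 0L)
  expect_error(advance_state(net, s0, c(Tll = 0L)), "Hkb")
  expect_error(advance_state(net, s0, c(Tll = 0L, Hkb = 0L),
                             genotype = "nope"), "wt")
})

test_that("simulate_genotype returns the declared tidy shape", {
  net <- terminal_network()
  traj <- simulate_genotype(net, "wt")
  expect_identical(nrow(traj), 4L * 4L * 7L)
  expect_named(traj, c("genotype", "region", "timepoint", "factor",
                       "level", "label"))
  expect_setequal(unique(traj$region), 1:4)
  expect_setequal(unique(traj$timepoint), 0:3)
  # t0: Cad on everywhere, other outputs off, inputs at schedule.
  t0 <- traj[traj$timepoint == 0, ]
  expect_true(all(t0$level[t0$factor == "Cad"] == 1L))
  expect_true(all(t0$level[t0$factor %in% c("D", "Opa", "Fkh", "Wg")] == 0L))
  expect_identical(t0$level[t0$factor == "Tll"][order(t0$region[t0$factor == "Tll"])],
                   c(0L, 1L, 2L, 2L))
  expect_error(simulate_genotype(net, "kni-"), "Unknown genotype")
})

test_that("input trajectories equal the schedule unless clamped", {
  net <- terminal_network()
  sched <- terminal_schedule()
  traj <- simulate_genotype(net, "wt")
  for (f in c("Tll", "Hkb")) {
    got <- traj[as.character(traj$factor) == f,
                c("region", "timepoint", "level")]
    want <- sched[sched$factor == f, c("region", "timepoint", "level")]
    merged <- merge(got, want, by = c("region", "timepoint"))
    expect_identical(merged$level.x, merged$level.y)
  }
  ko <- simulate_genotype(net, "tor-")
  expect_true(all(ko$level[ko$factor %in% c("Tll", "Hkb")] == 0L))
})

test_that("simulation is deterministic and regions are independent", {
  net <- terminal_network()
  expect_identical(simulate_genotypes(net), simulate_genotypes(net))
  # Locality: restricting the schedule to one region leaves that
  # region's trajectory untouched.
  full <- simulate_genotype(net, "wt")
  for (r in 1:4) {
    net_r <- net
    net_r$schedule <- net$schedule[net$schedule$region == r, ]
    net_r$schedule$region <- 1L
    solo <- simulate_genotype(net_r, "wt")
    a <- full[full$region == r, c("timepoint", "factor", "level")]
    b <- solo[, c("timepoint", "factor", "level")]
    expect_identical(a[order(a$factor, a$timepoint), ]$level,
                     b[order(b$factor, b$timepoint), ]$level)
  }
})

test_that("clamped factors are zero everywhere for every genotype", {
  net <- terminal_network()
  for (g in names(terminal_genotypes())) {
    traj <- simulate_genotype(net, g)
    for (f in terminal_genotypes()[[g]]) {
      expect_true(all(traj$level[traj$factor == f] == 0L),
                  label = paste(g, f))
    }
  }
})

test_that("engine matches brute-force recursive evaluation", {
  # Canonical network, every genotype.
  net <- terminal_network()
  for (g in names(terminal_genotypes())) {
    got <- as.data.frame(simulate_genotype(net, g)[
      , c("genotype", "region", "timepoint", "factor", "level")])
    got$factor <- as.character(got$factor)
    want <- oracle_trajectory(net, g)
    got <- got[order(got$region, got$timepoint, got$factor), ]
    want <- want[order(want$region, want$timepoint, want$factor), ]
    expect_equal(got$level, want$level, label = g)
  }
  # Small random threshold networks.
  withr::with_seed(42L, {
    for (i in 1:10) {
      rn <- random_network(n_outputs = sample(1:3, 1L))
      for (g in c("wt", "ko")) {
        got <- as.data.frame(simulate_genotype(rn, g)[
          , c("region", "timepoint", "factor", "level")])
        got$factor <- as.character(got$factor)
        want <- oracle_trajectory(rn, g)
        got <- got[order(got$region, got$timepoint, got$factor), ]
        want <- want[order(want$region, want$timepoint, want$factor), ]
        expect_equal(got$level, want$level)
      }
    }
  })
})

test_that("validate_network reports structural defects", {
  net <- terminal_network()
  expect_identical(nrow(validate_network(net)), 0L)

  bad_sched <- net
  bad_sched$schedule$level[bad_sched$schedule$factor == "Tll" &
                             bad_sched$schedule$region == 1 &
                             bad_sched$schedule$timepoint == 0] <- 3L
  v <- validate_network(bad_sched)
  expect_true("schedule_level_out_of_bounds" %in% v$check)

  bad_geno <- net
  bad_geno$genotypes$`kni-` <- "Kni"
  v2 <- validate_network(bad_geno)
  expect_true("genotype_clamps_unknown_factor" %in% v2$check)
  expect_match(v2$detail[v2$check == "genotype_clamps_unknown_factor"],
               "Kni")

  missing_cell <- net
  missing_cell$schedule <- missing_cell$schedule[-1L, ]
  expect_true("schedule_missing_cell" %in%
                validate_network(missing_cell)$check)

  dup <- net
  dup$factors <- rbind(dup$factors, dup$factors[1L, ])
  expect_true("duplicate_factor" %in% validate_network(dup)$check)

  no_rule <- net
  no_rule$rules$Wg <- NULL
  expect_true("missing_rule" %in% validate_network(no_rule)$check)
})

test_that("level labels follow the off/weak/strong vocabulary", {
  expect_identical(level_label(c(0, 1, 2), 2), c("off", "weak", "strong"))
  expect_identical(level_label(c(0, 1), 1), c("off", "on"))
})
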