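defs <- lapply(score_names(), builtin_definition)
names(defs) <- score_names()

test_that("built-in definitions expose the documented structure", {
  expect_setequal(defs$qSOFA$channels,
                  c("respiratory_rate", "systolic_bp", "consciousness"))
  expect_equal(defs$BTF$aggregation, "any_trigger")
  expect_equal(defs$NEWS$aggregation, "sum_of_points")
  # SIRS band-form criterion fires strictly above 10%
  expect_equal(component_points(defs$SIRS, "band_fraction", 10), 0L)
  expect_equal(component_points(defs$SIRS, "band_fraction", 10.5), 1L)
  expect_equal(defs$NEWS$max_value, 20L)
  expect_equal(defs$MEWS$max_value, 14L)
  expect_equal(defs$qSOFA$max_value, 3L)
  expect_equal(defs$SIRS$max_value, 4L)
  expect_equal(defs$BTF$max_value, 1L)
  expect_error(builtin_definition("NEWS2"), "unknown score")
})

test_that("component points honour published inclusive and strict bounds", {
  expect_equal(component_points(defs$qSOFA, "respiratory_rate", 22), 1L)
  expect_equal(component_points(defs$qSOFA, "respiratory_rate", 21), 0L)
  expect_equal(component_points(defs$qSOFA, "systolic_bp", 100), 1L)
  expect_equal(component_points(defs$qSOFA, "systolic_bp", 100.5), 0L)
  expect_equal(component_points(defs$SIRS, "heart_rate", 90), 0L)
  expect_equal(component_points(defs$SIRS, "heart_rate", 90.5), 1L)
  expect_equal(component_points(defs$NEWS, "heart_rate", 60), 0L)
  expect_error(component_points(defs$qSOFA, "temperature", 37),
               "not used by score")
  expect_error(component_points(defs$NEWS, "heart_rate", 400),
               "out of domain")
})

test_that("total_score aggregates per criterion with OR groups", {
  expect_equal(total_score(defs$qSOFA, c(respiratory_rate = 24,
                                         systolic_bp = 95,
                                         consciousness = 1)), 3L)
  state <- c(temperature = 38.5, heart_rate = 95, respiratory_rate = 18,
             wbc = 8, band_fraction = 0, paco2 = 40)
  expect_equal(total_score(defs$SIRS, state), 2L)
  # RR and PaCO2 are one criterion: both abnormal still one point
  state2 <- state
  state2[["respiratory_rate"]] <- 24; state2[["paco2"]] <- 30
  expect_equal(total_score(defs$SIRS, state2), 3L)
  expect_error(total_score(defs$qSOFA, c(respiratory_rate = 24)),
               "missing channel")
  for (d in defs)
    expect_equal(total_score(d, normal_defaults()[d$channels]), 0L)
})

test_that("bands partition every channel domain: exactly one band matches", {
  reg <- ews_channels()
  set.seed(42)
  for (d in defs) {
    for (ch in d$channels) {
      b <- d$bands[d$bands$channel == ch, ]
      r <- reg[reg$channel == ch, ]
      vals <- c(runif(10000, r$lo, r$hi), r$lo, r$hi,
                b$lower[is.finite(b$lower)])
      # a value's band is the one with the greatest satisfied lower bound;
      # the lowest band starts at -Inf closed, so exactly one band matches
      sat <- sapply(seq_len(nrow(b)), function(k)
        if (b$lower_open[k]) vals > b$lower[k] else vals >= b$lower[k])
      expect_true(all(sat[, 1]),
                  label = sprintf("%s/%s lowest band catches all", d$name, ch))
      idx <- apply(sat, 1, function(s) max(which(s)))
      expect_equal(component_points(d, ch, vals), b$points[idx])
    }
  }
})

test_that("points are monotone as values move away from the normal default", {
  reg <- ews_channels()
  for (d in defs) {
    for (ch in d$channels) {
      r <- reg[reg$channel == ch, ]
      normal <- normal_defaults()[[ch]]
      up <- seq(normal, r$hi, length.out = 200)
      down <- seq(normal, r$lo, length.out = 200)
      expect_true(all(diff(component_points(d, ch, up)) >= 0),
                  label = sprintf("%s/%s upper tail monotone", d$name, ch))
      expect_true(all(diff(component_points(d, ch, down)) >= 0),
                  label = sprintf("%s/%s lower tail monotone", d$name, ch))
    }
  }
})

test_that("scores stay within documented ranges on random states", {
  reg <- ews_channels()
  set.seed(7)
  for (rep in 1:200) {
    state <- vapply(reg$channel, function(ch) {
      r <- reg[reg$channel == ch, ]
      if (ch == "consciousness") sample(0:3, 1)
      else if (ch == "supplemental_o2") sample(0:1, 1)
      else runif(1, r$lo, r$hi)
    }, numeric(1))
    for (d in defs) {
      s <- total_score(d, state[d$channels])
      expect_gte(s, 0L)
      expect_lte(s, d$max_value)
      if (d$aggregation == "any_trigger") expect_true(s %in% c(0L, 1L))
    }
  }
})

test_that("custom definitions load from the documented file format", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("channel,criterion,lower,lower_open,upper,points",
               "heart_rate,heart_rate,-Inf,FALSE,100,0",
               "heart_rate,heart_rate,100,FALSE,Inf,2"), path)
  d <- load_score_definition(path, "custom", "sum_of_points", 2L)
  expect_equal(component_points(d, "heart_rate", 99), 0L)
  expect_equal(component_points(d, "heart_rate", 100), 2L)
  # malformed: gap between bands
  writeLines(c("channel,criterion,lower,lower_open,upper,points",
               "heart_rate,heart_rate,-Inf,FALSE,90,0",
               "heart_rate,heart_rate,100,FALSE,Inf,2"), path)
  expect_error(load_score_definition(path, "bad", "sum_of_points"),
               "do not chain")
})
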