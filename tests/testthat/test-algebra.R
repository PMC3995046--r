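test_that("the printed channel equations parse into the expected trees", {
  eq <- parse_equations("chan33=chan27−chan26 label VEOG")[[1]]  # typographic minus
  expect_equal(eq$target_kind, "chan")
  expect_equal(eq$target_index, 33L)
  expect_equal(eq$label, "VEOG")
  expect_equal(eq$ast$t, "bin2")
  expect_equal(eq$ast$op, "-")
  expect_equal(eq$ast$a$index, 27L)
  expect_equal(eq$ast$b$index, 26L)

  eq2 <- parse_equations("newchan1=sqrt(chan1ˆ2+chan2ˆ2)+5")[[1]]  # printed circumflex
  expect_equal(eq2$target_kind, "newchan")
  expect_equal(eq2$ast$op, "+")
  expect_equal(eq2$ast$a$t, "call")
  expect_equal(eq2$ast$a$fn, "sqrt")
  expect_equal(eq2$ast$a$a$a$op, "^")

  eq3 <- parse_equations("chan14=avgchan(10,12,16,18)")[[1]]
  expect_equal(eq3$ast$t, "avgchan")
  expect_equal(unlist(eq3$ast$ranges), c(10, 10, 12, 12, 16, 16, 18, 18))
})

test_that("parse errors name line numbers; chan/bin mixing is rejected", {
  expect_error(parse_equations(c("chan1=chan2", "chan3=foo(chan1)")),
               "line 2.*unknown function")
  expect_error(parse_equations("bin3=chan1-bin1"),
               "chanN operands are not allowed in bin equations")
  expect_error(parse_equations("chan3=bin1"),
               "binN operands are not allowed in chan equations")
  expect_error(parse_equations("bin2=avgchan(1:3)"),
               "avgchan\\(\\) is only allowed in channel equations")
  expect_error(parse_equations("chan1=avgchan(5:2)"), "malformed range")
  expect_error(parse_equations("foo1=chan1"), "target must be")
})

test_that("power is right-associative and unary minus parses", {
  eq <- parse_equations("chan1=chan1^2^3")[[1]]
  expect_equal(eq$ast$op, "^")
  expect_equal(eq$ast$b$op, "^")   # 2^(3) nested on the right
  eqm <- parse_equations("chan1=-chan2+1")[[1]]
  expect_equal(eqm$ast$op, "+")
  expect_equal(eqm$ast$a$t, "neg")
})

test_that("pretty-printed equations re-parse to identical trees", {
  texts <- c("chan33=chan27-chan26 label VEOG",
             "newchan1=sqrt(chan1^2+chan2^2)+5",
             "chan14=avgchan(10,12,16,18)",
             "chan2=-chan1*3.5/(chan2+1)",
             "bin5=abs(bin1+bin2+bin3+bin4)",
             "newbin3=bin1@Left+bin2@Right")
  for (tx in texts) {
    eq <- parse_equations(tx)[[1]]
    eq2 <- parse_equations(deparse_equation(eq))[[1]]
    eq$text <- eq2$text <- NULL
    expect_equal(eq2[c("target_kind", "target_index", "ast", "label")],
                 eq[c("target_kind", "target_index", "ast", "label")])
  }
})

test_that("channel operations compute the printed examples", {
  vals <- c(rep(0, 25), 5, 12, rep(0, 5))   # chans 26 = 5, 27 = 12 of 32
  eeg <- make_constant_eeg(vals, n_samples = 50)
  out <- apply_channel_ops(eeg, parse_equations("chan33=chan27-chan26 label VEOG"))
  expect_equal(nrow(out$data), 33L)
  expect_true(all(out$data[33, ] == 7))
  expect_equal(out$chan_labels[33], "VEOG")

  eeg2 <- make_constant_eeg(c(3, 4), n_samples = 50)
  out2 <- apply_channel_ops(eeg2, parse_equations("newchan1=sqrt(chan1^2+chan2^2)+5"))
  expect_true(all(abs(out2$data[1, ] - 10) < 1e-12))  # 3-4-5 triangle + 5

  vals3 <- rep(0, 18); vals3[c(10, 12, 16, 18)] <- c(1, 2, 3, 4)
  eeg3 <- make_constant_eeg(vals3, n_samples = 50)
  out3 <- apply_channel_ops(eeg3, parse_equations("chan14=avgchan(10,12,16,18)"))
  expect_equal(nrow(out3$data), 18L)              # interpolation replaces in place
  expect_true(all(out3$data[14, ] == 2.5))
})

test_that("chanK equations are sequential while newchanK sees the snapshot", {
  eeg <- make_constant_eeg(c(1, 10), n_samples = 20)
  # sequential: second equation sees the first's result
  seqout <- apply_channel_ops(eeg, parse_equations(c("chan1=chan1+100",
                                                     "chan2=chan1")))
  expect_true(all(seqout$data[2, ] == 101))
  # snapshot: both newchan equations see original data
  snap <- apply_channel_ops(eeg, parse_equations(c("newchan1=chan1+100",
                                                   "newchan2=chan1")))
  expect_true(all(snap$data[1, ] == 101))
  expect_true(all(snap$data[2, ] == 1))

  expect_error(apply_channel_ops(eeg, parse_equations("chan9=chan1")),
               "index gap")
  expect_error(apply_channel_ops(eeg, parse_equations("chan1=chan7")),
               "nonexistent channel")
  expect_error(apply_channel_ops(eeg, parse_equations("chan1=chan2/0")),
               "division by zero")
})

test_that("channel operations work identically on epoched and averaged data", {
  ep <- make_constant_epochs(matrix(c(1, 2, 3, 4), 2, byrow = FALSE))
  oute <- apply_channel_ops(ep, parse_equations("chan3=chan2-chan1"))
  expect_equal(dim(oute$data)[2], 3L)
  expect_true(all(oute$data[, 3, ] == 2))

  erp <- make_constant_erp(matrix(c(1, 4, 2, 8), 2))   # 2 bins x 2 chans
  outr <- apply_channel_ops(erp, parse_equations("chan3=chan2-chan1"))
  expect_equal(outr$data[1, 3, 1], 1)
  expect_equal(outr$data[2, 3, 1], 4)
})

test_that("the reference assistant emits the printed equations, which re-parse and apply", {
  eqs <- reference_assistant(1:3, "1:32,38:50")
  expect_equal(eqs, c("newchan1=chan1-avgchan(1:32,38:50)",
                      "newchan2=chan2-avgchan(1:32,38:50)",
                      "newchan3=chan3-avgchan(1:32,38:50)"))
  expect_length(parse_equations(eqs), 3L)
  expect_equal(reference_assistant(5, 7), "newchan5=chan5-avgchan(7)")
  expect_equal(reference_assistant(1, c(1, 2, 3, 8)),
               "newchan1=chan1-avgchan(1:3,8)")
  expect_error(reference_assistant(integer(), 1), "no channels")
})

test_that("re-referencing every channel to the common average zeroes the channel mean", {
  set.seed(9)
  eeg <- continuous_eeg(matrix(rnorm(6 * 200), 6), srate = 500)
  eqs <- parse_equations(reference_assistant(1:6, 1:6))
  out <- apply_channel_ops(eeg, eqs)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
})

test_that("equation evaluation matches a reference interpreter on random trees", {
  set.seed(10)
  for (rep in 1:50) {
    n_chan <- 4
    eeg <- continuous_eeg(matrix(rnorm(n_chan * 30), n_chan), srate = 500)
    txt <- paste0("chan", n_chan + 1, "=", random_expr_text(n_chan))
    eq <- parse_equations(txt)[[1]]
    out <- apply_channel_ops(eeg, list(eq))
    chan_data <- lapply(seq_len(n_chan), function(k) eeg$data[k, ])
    want <- eval_ast_reference(eq$ast, chan_data)
    expect_equal(out$data[n_chan + 1, ], rep(want, length.out = 30), tolerance = 1e-12)
  }
})

test_that("bin operations compute difference waves with linear identity and labels", {
  erp <- make_constant_erp(c(1, 4), n_accepted = c(50, 12))
  out <- apply_bin_ops(erp, parse_equations("bin3=bin2-bin1 label Oddball-Minus-Standard"))
  expect_equal(out$data[3, 1, 1], 3)
  expect_equal(out$bin_labels[3], "Oddball-Minus-Standard")
  expect_equal(out$counts$n_accepted[3], 12L)   # min of operand counts
  # difference-wave linearity: bin3 + bin1 == bin2 exactly
  expect_identical(out$data[3, , ] + out$data[1, , ], out$data[2, , ])

  erp4 <- make_constant_erp(c(1, -2, 3, -4))
  out4 <- apply_bin_ops(erp4, parse_equations("bin5=abs(bin1+bin2+bin3+bin4)"))
  expect_equal(out4$data[5, 1, 1], 2)
})

test_that("electrode groups pair channels positionally and reshape the output", {
  # 4 channels; bin1 holds (1,2,3,4), bin2 holds (10,20,30,40)
  erp <- make_constant_erp(matrix(c(1:4, c(10, 20, 30, 40)), 2, byrow = TRUE))
  groups <- parse_electrode_groups(c("Left: 1,2", "Right: 3,4"))
  out <- apply_bin_ops(erp, parse_equations("newbin3=bin1@Left+bin2@Right"), groups)
  expect_equal(dim(out$data)[2], 2L)
  expect_equal(out$data[3, 1, 1], 1 + 30)   # Left[1] + Right[1]
  expect_equal(out$data[3, 2, 1], 2 + 40)
  expect_equal(out$chan_labels, c("ch1", "ch2"))

  bad <- parse_electrode_groups(c("Left: 1,2", "Right: 3"))
  expect_error(apply_bin_ops(erp, parse_equations("newbin3=bin1@Left+bin2@Right"), bad),
               "group length mismatch")
  expect_error(apply_bin_ops(erp, parse_equations("newbin3=bin1@Left+bin2"),
                             parse_electrode_groups("Left: 1,2")),
               "different widths")
})
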