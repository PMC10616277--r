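test_that("severity bands sit exactly at the published boundaries", {
  expect_equal(severity_class("vqids", 6), "moderate_severe")
  expect_equal(severity_class("vqids", 5), "mild")
  expect_equal(severity_class("vqids", 4), "none")
  expect_equal(severity_class("gad7", 10), "moderate_severe")
  expect_equal(severity_class("gad7", 9), "mild")
  expect_equal(severity_class("gad7", 5), "mild")
  expect_equal(severity_class("gad7", 4), "none")
  expect_equal(severity_class("vqids", NA), "none")
  expect_error(severity_class("vqids", 16), "range")
  expect_error(severity_class("gad7", -1), "range")
})

test_that("exacerbation needs one moderate score or two cross-instrument milds", {
  sv <- function(v1, g1, v2, g2)
    data.frame(week = c(3, 4), vqids_sr5 = c(v1, v2), gad7 = c(g1, g2))
  expect_true(assess_exacerbation(sv(7, 2, 1, 2), 3))     # moderate VQIDS at w
  expect_true(assess_exacerbation(sv(1, 1, 1, 11), 3))    # moderate GAD at w+1
  expect_true(assess_exacerbation(sv(5, 2, 2, 6), 3))     # mild VQIDS + mild GAD
  expect_false(assess_exacerbation(sv(4, 4, 4, 4), 3))    # all below mild
  expect_false(assess_exacerbation(sv(5, 2, 5, 2), 3))    # two mild VQIDS only
  # the alternative reading: same instrument mild in both weeks
  expect_true(assess_exacerbation(sv(5, 2, 5, 2), 3,
                                  mild_rule = "same_instrument_both_weeks"))
  expect_false(assess_exacerbation(sv(5, 2, 2, 6), 3,
                                   mild_rule = "same_instrument_both_weeks"))
  # fully missing window is non-exacerbating
  expect_false(assess_exacerbation(sv(NA, NA, NA, NA), 3))
  expect_false(assess_exacerbation(sv(4, 4, 4, 4), 99))   # no such weeks
})

test_that("the relapse flag requires passive AND active", {
  expect_true(combined_decision(TRUE, TRUE))
  expect_false(combined_decision(TRUE, FALSE))
  expect_false(combined_decision(FALSE, TRUE))
  expect_false(combined_decision(FALSE, FALSE))
})

test_that("visit labeling follows the relapse criteria table", {
  expect_equal(label_visit(visit_row(22, ver = 23)), "relapse")
  expect_equal(label_visit(visit_row(22, ver = 18, cgis = 4, baseline = 2)),
               "relapse")                       # CGI-S change >= 2
  expect_equal(label_visit(visit_row(21)), "non_relapse")
  expect_equal(label_visit(visit_row(25, ver = 15, cgis = 3, baseline = 2,
                                     med = FALSE)), "non_relapse")
  expect_equal(label_visit(visit_row(25, ver = 15, cgis = 3, baseline = 2,
                                     med = TRUE)), "relapse")
  expect_equal(label_visit(visit_row(5, hosp = TRUE)), "relapse")
  expect_equal(label_visit(visit_row(5, suic = TRUE)), "relapse")
  expect_equal(label_visit(visit_row(5, inv = TRUE)), "relapse")
  expect_error(label_visit(visit_row(25)), "unresolved")
  expect_error(label_visit(visit_row(NA)), "MADRS")
})
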