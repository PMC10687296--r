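# Shared test fixtures, built in code.

# a small valid 2x2-balanced toy for error-path tests is not needed; the
# real L36 array loads in milliseconds and is reused across tests
l36 <- annL36::oa_l36()

fixture_table <- annL36::ann_training_table()

# dataset planted by a known 23-weight network whose non-zero weights all
# lie on the initial Taguchi level grid: output = 1 - sigmoid(-f8), i.e.
# W19 = -1 (base-rate input of hidden 2), W22 = -1, W23 = +1.
planted_grid_dataset <- function(coding = "fuzzy") {
  ds <- annL36::ann_dataset(fixture_table, coding = coding)
  w <- rep(0, 23)
  w[19] <- -1; w[22] <- -1; w[23] <- 1
  net <- annL36::build_network(w)
  y_new <- ds$decode(predict(net, ds$X))
  stopifnot(all(y_new > 0))
  tab <- fixture_table
  tab$prevalence <- y_new
  annL36::ann_dataset(tab, coding = coding)
}
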