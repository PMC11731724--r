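test_that("channel replication shares FSI and CxI only", {
  pf <- cbgt_paramfile("n-choice")
  net <- build_network(pf, c("left", "right"), seed = 1)
  pops <- net$pops
  expect_equal(sum(pops$base == "FSI"), 1)
  expect_equal(sum(pops$base == "CxI"), 1)
  for (b in setdiff(unique(pops$base), c("FSI", "CxI")))
    expect_equal(sum(pops$base == b), 2)
  net3 <- build_network(pf, c("a", "b", "c"), seed = 1)
  expect_equal(sum(net3$pops$base == "FSI"), 1)
  expect_equal(sum(net3$pops$base == "Th"), 3)
})

test_that("con = 1 between sizes 5 and 7 realizes exactly 35 connections", {
  pf <- toy_paramfile()
  net <- build_network(pf, "only", seed = 4)
  expect_equal(net$pathways$n_connections, 35)
  expect_equal(sum(net$W_static$AMPA != 0), 35)
})

test_that("realized connection counts stay within binomial 99% bounds", {
  pf <- toy_paramfile(sizes = c(Cx = 50, Th = 50),
                      pathways = data.frame(src = "Cx", dest = "Th",
                                            receptor = "AMPA", type = "syn",
                                            con = 0.5, eff = 1e-3,
                                            plastic = FALSE))
  counts <- vapply(1:6, function(s)
    build_network(pf, "only", seed = s)$pathways$n_connections, numeric(1))
  bounds <- qbinom(c(0.005, 0.995), 2500, 0.5)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
  expect_gt(length(unique(counts)), 1)  # genuinely stochastic
})

test_that("rebuilding with the same seed reproduces the adjacency", {
  pf <- cbgt_paramfile("n-choice")
  a <- build_network(pf, c("left", "right"), seed = 9)
  b <- build_network(pf, c("left", "right"), seed = 9)
  expect_identical(a$W_static, b$W_static)
  expect_identical(a$pathways$n_connections, b$pathways$n_connections)
  expect_identical(a$V0, b$V0)
})

test_that("newpathways overrides and appends; GPe resolves to GPeP", {
  pf <- cbgt_paramfile("n-choice")
  base <- normalizePathways <- pf$pathways
  expect_identical(apply_newpathways(base, NULL), base)
  # the cortico-pallidal example row: appended with its printed fields
  row <- data.frame("Cx", "GPe", "AMPA", "syn", 0.5, 0.01, FALSE,
                    stringsAsFactors = FALSE)
  merged <- apply_newpathways(base, row)
  expect_equal(nrow(merged), nrow(base) + 1)
  added <- merged[nrow(merged), ]
  expect_equal(added$dest, "GPeP")
  expect_equal(added$con, 0.5)
  expect_equal(added$eff, 0.01)
  expect_false(added$plastic)
  # overriding an existing row changes it in place
  ov <- data.frame("Cx", "Th", "AMPA", "syn", 1.0, 0.9, FALSE)
  merged2 <- apply_newpathways(base, ov)
  expect_equal(nrow(merged2), nrow(base))
  hit <- merged2$src == "Cx" & merged2$dest == "Th" & merged2$receptor == "AMPA"
  expect_equal(merged2$eff[hit], 0.9)
  # list of tables applied in order
  both <- apply_newpathways(base, list(row, ov))
  expect_equal(nrow(both), nrow(base) + 1)
  expect_error(apply_newpathways(base, data.frame("Cx", "Nowhere", "AMPA",
                                                  "syn", 0.5, 0.1, FALSE)),
               "valid names")
})

test_that("changing only the efficacy of a pathway keeps its topology", {
  pf <- toy_paramfile(sizes = c(Cx = 30, Th = 30),
                      pathways = data.frame(src = "Cx", dest = "Th",
                                            receptor = "AMPA", type = "syn",
                                            con = 0.5, eff = 0.001,
                                            plastic = FALSE))
  net <- build_network(pf, "only", seed = 2)
  net2 <- apply_newpathways(net, data.frame("Cx", "Th", "AMPA", "syn",
                                            0.5, 0.005, FALSE))
  expect_equal((net2$W_static$AMPA != 0), (net$W_static$AMPA != 0))
  expect_equal(net2$W_static$AMPA[net2$W_static$AMPA != 0],
               rep(0.005, net$pathways$n_connections))
  net3 <- apply_newpathways(net, data.frame("Cx", "Th", "AMPA", "syn",
                                            0.9, 0.001, FALSE))
  expect_gt(net3$pathways$n_connections, net$pathways$n_connections)
})

test_that("shared-input scaling keeps expected drive invariant in n_channels", {
  tbl <- data.frame(src = c("Cx", "FSI", "Cx"), dest = c("FSI", "dSPN", "Th"),
                    receptor = "AMPA", type = c("common", "syn", "syn"),
                    con = 1, eff = c(0.01, 0.02, 0.03), plastic = FALSE)
  expect_identical(scale_shared_inputs(tbl, 1), tbl)
  s2 <- scale_shared_inputs(tbl, 2)
  expect_equal(s2$eff, c(0.005, 0.02, 0.03))  # only channelized -> shared
  s4 <- scale_shared_inputs(tbl, 4)
  expect_equal(s4$eff[1], s2$eff[1] / 2)      # doubling halves again
  expect_error(scale_shared_inputs(tbl, 0), "n_channels")

  # realized total synaptic weight onto each FSI neuron is independent of the
  # number of channels (con = 1 makes the accounting exact)
  pf <- cbgt_paramfile("n-choice")
  w_onto_fsi <- function(n_ch) {
    chans <- paste0("c", seq_len(n_ch))
    net <- build_network(pf, chans, seed = 3)
    fsi <- cbgt:::pop_neurons(net, "FSI")
    sum(net$W_static$AMPA[fsi, ])
  }
  expect_equal(w_onto_fsi(2), w_onto_fsi(1), tolerance = 1e-10)
  expect_equal(w_onto_fsi(3), w_onto_fsi(1), tolerance = 1e-10)
})

test_that("plastic pathways are tracked per channel with their weights", {
  pf <- cbgt_paramfile("n-choice")
  net <- build_network(pf, c("left", "right"), seed = 5)
  w <- cbgt:::weights_state(net)
  expect_setequal(w$channel, c("left", "right"))
  expect_setequal(w$target, c("dSPN", "iSPN"))
  expect_equal(nrow(w), 4)
  expect_true(all(w$w == pf$dSPNdefaults$dpmn_w0))
})
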