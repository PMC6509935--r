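# Synchronous stepping, trajectories and exhaustive enumeration.

test_that("the all-zero state steps to CDK1-AurA alone", {
    net <- faChkrecNetwork()
    s1 <- stepState(net, rep(0L, 25))
    expect_identical(names(which(s1 == 1L)), "CDK1-AurA")
    # agrees with the independent evaluator
    expect_identical(oracle_step(net, makeState(nodes(net))), s1)
})

test_that("clamps override rules at every step", {
    net <- faChkrecNetwork()
    s <- makeState(nodes(net), c("ICL", "NUC1"))
    s1 <- stepState(net, s, clamps = c(ICL = 1L))
    expect_identical(unname(s1[["ICL"]]), 1L)      # rule alone would clear it
    expect_identical(unname(stepState(net, s)[["ICL"]]), 0L)
    expect_error(stepState(net, s, clamps = c(NOPE = 1L)), "unknown clamp")
})

test_that("trajectories split into transient and cycle correctly", {
    net <- faChkrecNetwork()
    tr <- simulateTrajectory(net, makeState(nodes(net)))
    # from rest the system settles in the CCP fixed point
    expect_identical(period(tr@attractor), 1L)
    fp <- attractorStates(tr@attractor)[1L, ]
    expect_identical(names(which(fp == 1L)),
                     c("CDK1-AurA", "PLK1", "CDC25", "CycB-CDK1"))
    # transient states are distinct and none lies on the cycle
    keys <- apply(tr@transient, 1L, paste, collapse = "")
    expect_false(anyDuplicated(keys) > 0L)
    expect_false(oracle_key(fp) %in% keys)

    # identity network: transient length 0, period 1, from any state
    id <- parseRules(c("A <- A", "B <- B"))
    for (code in 0:3) {
        tr <- simulateTrajectory(id, decodeState(code, nodes(id)))
        expect_identical(nrow(tr@transient), 0L)
        expect_identical(period(tr@attractor), 1L)
    }
})

test_that("a persistent ICL clamp keeps the division switch off", {
    net <- faChkrecNetwork()
    tr <- simulateTrajectory(net, makeState(nodes(net), "ICL"),
                             clamps = c(ICL = 1L))
    s <- attractorStates(tr@attractor)
    expect_true(all(s[, "ICL"] == 1L))            # clamped throughout
    expect_true(all(s[, "CycB-CDK1"] == 0L))      # no mitotic entry
    expect_true(period(tr@attractor) > 1L)        # cyclic arrest attractor
})

test_that("the step budget error is explicit", {
    net <- faChkrecNetwork()
    expect_error(simulateTrajectory(net, makeState(nodes(net)), maxSteps = 2),
                 "budget")
    expect_error(simulateTrajectory(net, makeState(nodes(net)), maxSteps = 0),
                 "maxSteps")
})

test_that("identity networks have 2^n fixed points with unit basins", {
    id <- parseRules(c("A <- A", "B <- B", "C <- C", "D <- D"))
    atts <- enumerateAttractors(id)
    expect_length(atts, 16L)
    for (i in seq_len(16L)) {
        expect_identical(period(atts[[i]]), 1L)
        expect_identical(basinSize(atts[[i]]), 1)
    }
})

test_that("the compiled engine matches the brute-force oracle", {
    for (seed in c(1L, 7L, 23L)) {
        net <- randomNetwork(7, 2, seed = seed)
        atts <- enumerateAttractors(net)
        want <- oracle_attractors(net)
        got <- set_cycle_keys(atts)
        expect_setequal(got, names(want))
        for (i in seq_len(length(atts))) {
            k <- got[i]
            expect_identical(basinSize(atts[[i]]), want[[k]][1],
                             label = sprintf("basin, seed %d", seed))
            expect_identical(as.numeric(period(atts[[i]])), want[[k]][2],
                             label = sprintf("period, seed %d", seed))
        }
        # basins partition the initial space
        expect_identical(sum(vapply(seq_len(length(atts)),
                                    function(i) basinSize(atts[[i]]),
                                    numeric(1))),
                         2^7)
    }
})

test_that("the engine matches the oracle under clamps", {
    net <- randomNetwork(6, 2, seed = 11)
    cl <- c(X2 = 1L, X5 = 0L)
    atts <- enumerateAttractors(net, clamps = cl)
    # oracle over the projected space: free assignments of the other nodes
    inits <- Filter(function(code) {
        s <- decodeState(code, nodes(net))
        s[["X2"]] == 1L && s[["X5"]] == 0L
    }, 0:63)
    want <- oracle_attractors(net, clamps = cl, inits = inits)
    expect_setequal(set_cycle_keys(atts), names(want))
    expect_identical(atts@initialSpaceSize, 2^4)
    expect_identical(sum(vapply(seq_len(length(atts)),
                                function(i) basinSize(atts[[i]]), numeric(1))),
                     2^4)
    # clamped nodes constant across every attractor
    for (i in seq_len(length(atts))) {
        s <- attractorStates(atts[[i]])
        expect_true(all(s[, "X2"] == 1L) && all(s[, "X5"] == 0L))
    }
})

test_that("explicit initial states restrict the basin partition", {
    net <- randomNetwork(6, 2, seed = 3)
    starts <- c(0, 5, 9, 33, 60)
    atts <- enumerateAttractors(net, initialStates = starts)
    expect_identical(atts@initialSpaceSize, length(starts) + 0)
    expect_identical(sum(vapply(seq_len(length(atts)),
                                function(i) basinSize(atts[[i]]), numeric(1))),
                     length(starts) + 0)
    want <- oracle_attractors(net, inits = starts)
    expect_setequal(set_cycle_keys(atts), names(want))
})

test_that("cycle validity: step maps each attractor state to the next", {
    net <- randomNetwork(8, 2, seed = 5)
    atts <- enumerateAttractors(net)
    for (i in seq_len(length(atts))) {
        s <- attractorStates(atts[[i]])
        p <- nrow(s)
        for (r in seq_len(p)) {
            nxt <- stepState(net, s[r, ])
            expect_identical(unname(nxt), unname(s[(r %% p) + 1L, ]))
        }
    }
})

test_that("exhaustive mode refuses oversized state spaces", {
    big <- randomNetwork(26, 2, seed = 1)
    expect_error(enumerateAttractors(big), "too large")
    # clamping below the threshold makes it legal again
    cl <- stats::setNames(rep(0L, 1), "X1")
    expect_error(enumerateAttractors(big, clamps = cl), NA)
})

test_that("enumeration is deterministic and canonically ordered", {
    net <- randomNetwork(8, 3, seed = 2)
    a1 <- enumerateAttractors(net)
    a2 <- enumerateAttractors(net)
    expect_identical(as.data.frame(a1), as.data.frame(a2))
    # canonical rotation: first state of each cycle has the smallest code
    for (i in seq_len(length(a1))) {
        codes <- apply(attractorStates(a1[[i]]), 1L, encodeState,
                       nodes = nodes(net))
        expect_identical(which.min(codes), 1L)
    }
})
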