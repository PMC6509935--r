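# Signed interaction graph derivation.

test_that("edge signs on the built-in model match hand-derivable cases", {
    edges <- deriveSignedEdges(faChkrecNetwork())
    sig <- function(src, tgt) edges$sign[edges$source == src & edges$target == tgt]
    expect_identical(sig("p53", "p21"), "positive")
    expect_identical(sig("WIP1", "p53"), "negative")
    expect_identical(sig("FANCD2I", "FANCD2I"), "negative")  # self-inhibition
    expect_identical(sig("ICL", "FAcore"), "positive")
    # WIP1 does not regulate p21 at all
    expect_length(sig("WIP1", "p21"), 0L)
})

test_that("every witness context verifies its claimed sign", {
    net <- faChkrecNetwork()
    edges <- deriveSignedEdges(net)
    parse_witness <- function(w) {
        if (w == "(empty)") return(stats::setNames(integer(0), character(0)))
        kv <- strsplit(strsplit(w, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
        stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                        vapply(kv, `[`, "", 1L))
    }
    for (i in seq_len(nrow(edges))) {
        rule <- rules(net)[[edges$target[i]]]
        u <- edges$source[i]
        if (nzchar(edges$witnessPos[i])) {
            ctx <- parse_witness(edges$witnessPos[i])
            lo <- evaluateRule(rule, c(ctx, stats::setNames(0L, u)))
            hi <- evaluateRule(rule, c(ctx, stats::setNames(1L, u)))
            expect_identical(c(lo, hi), c(0L, 1L),
                             label = paste("positive witness", u, "->", edges$target[i]))
        }
        if (nzchar(edges$witnessNeg[i])) {
            ctx <- parse_witness(edges$witnessNeg[i])
            lo <- evaluateRule(rule, c(ctx, stats::setNames(0L, u)))
            hi <- evaluateRule(rule, c(ctx, stats::setNames(1L, u)))
            expect_identical(c(lo, hi), c(1L, 0L),
                             label = paste("negative witness", u, "->", edges$target[i]))
        }
        expect_true(nzchar(edges$witnessPos[i]) || nzchar(edges$witnessNeg[i]))
    }
})

test_that("sign derivation agrees with a full truth-table oracle", {
    for (seed in c(2L, 9L)) {
        net <- randomNetwork(6, 3, seed = seed)
        edges <- deriveSignedEdges(net)
        for (tgt in nodes(net)) {
            rule <- rules(net)[[tgt]]
            vars <- all.vars(rule)
            for (u in vars) {
                # oracle: exhaustive loop over all contexts, base eval only
                others <- setdiff(vars, u)
                pos <- neg <- FALSE
                grid <- if (length(others))
                    expand.grid(rep(list(0:1), length(others)))
                else data.frame(row.names = 1)
                for (r in seq_len(nrow(grid))) {
                    ctx <- if (length(others))
                        stats::setNames(as.integer(grid[r, ]), others)
                    else stats::setNames(integer(0), character(0))
                    f0 <- oracle_eval(rule, c(ctx, stats::setNames(0L, u)))
                    f1 <- oracle_eval(rule, c(ctx, stats::setNames(1L, u)))
                    if (f0 < f1) pos <- TRUE
                    if (f0 > f1) neg <- TRUE
                }
                want <- if (pos && neg) "dual"
                        else if (pos) "positive"
                        else if (neg) "negative"
                        else NA_character_
                got <- edges$sign[edges$source == u & edges$target == tgt]
                if (is.na(want)) {
                    expect_length(got, 0L)
                    inert <- attr(edges, "inert")
                    expect_true(any(inert$source == u & inert$target == tgt))
                } else {
                    expect_identical(got, want,
                                     label = sprintf("%s -> %s, seed %d", u, tgt, seed))
                }
            }
        }
    }
})

test_that("edge summaries aggregate counts and degrees", {
    toy <- parseRules(c("A <- B", "B <- !A"))
    s <- edgeSummary(deriveSignedEdges(toy))
    expect_identical(unname(s$counts[c("total", "positive", "negative", "dual")]),
                     c(2L, 1L, 1L, 0L))
    empty <- edgeSummary(deriveSignedEdges(parseRules("A <- 0 | A"))[0, ])
    expect_identical(unname(empty$counts[["total"]]), 0L)

    # the full model: totals decompose; counts are reproducible facts of the
    # logic, not transcribed claims
    full <- edgeSummary(deriveSignedEdges(faChkrecNetwork()))
    expect_identical(unname(full$counts[["total"]]),
                     unname(full$counts[["positive"]] + full$counts[["negative"]] +
                            full$counts[["dual"]]))
    expect_true(full$counts[["total"]] > 100L)
})

test_that("context explosion is guarded", {
    net <- randomNetwork(18, 2, seed = 4)
    expect_error(deriveSignedEdges(net, maxInputs = 1L), "refused")
})

test_that("SIF export is one line per edge", {
    edges <- deriveSignedEdges(parseRules(c("A <- B", "B <- !A")))
    lines <- writeSIF(edges)
    expect_length(lines, 2L)
    expect_true(all(grepl("^[AB]\t(positive|negative)\t[AB]$", lines)))
})
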