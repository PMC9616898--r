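ev_type <- function(A, B, strand = "+")
  classify_event(make_tm(A, strand, tx = "tA"),
                 make_tm(B, strand, tx = "tB"))$event_type

test_that("canonical event shapes classify to their types with coords", {
  e1 <- c(0, 100); e2 <- c(200, 300); e3 <- c(400, 500)
  # cassette exon with shared flanks
  se <- classify_event(make_tm(rbind(e1, e2, e3), tx = "a"),
                       make_tm(rbind(e1, e3), tx = "b"))
  expect_equal(se$event_type, "SE")
  expect_equal(unname(se$event_coords), matrix(e2, 1))
  # retained intron
  ri <- classify_event(make_tm(rbind(c(0, 100), c(200, 300)), tx = "a"),
                       make_tm(rbind(c(0, 300)), tx = "b"))
  expect_equal(ri$event_type, "RI")
  expect_equal(unname(ri$event_coords), matrix(c(100, 200), 1))
  # identical chains carry no coords
  id <- classify_event(make_tm(rbind(e1, e2), tx = "a"),
                       make_tm(rbind(e1, e2), tx = "b"))
  expect_equal(id$event_type, "identical")
  expect_null(id$event_coords)
  # mutually exclusive internal exons between shared flanks
  expect_equal(ev_type(rbind(e1, c(150, 180), e3),
                       rbind(e1, c(250, 280), e3)), "MX")
  # alternative first/last exons (plus strand)
  expect_equal(ev_type(rbind(c(0, 50), e2, e3), rbind(c(60, 90), e2, e3)),
               "AF")
  expect_equal(ev_type(rbind(e1, e2, c(400, 450)), rbind(e1, e2, c(460, 500))),
               "AL")
})

test_that("splice-site labels follow transcription direction", {
  e1 <- c(0, 100); e3 <- c(400, 500)
  varied_start <- function(s) rbind(e1, c(s, 300), e3)
  # internal acceptor (genomic start) on plus strand: A3
  expect_equal(ev_type(varied_start(200), varied_start(220), "+"), "A3")
  # same geometry on minus strand is the donor side: A5
  expect_equal(ev_type(varied_start(200), varied_start(220), "-"), "A5")
  varied_end <- function(e) rbind(e1, c(200, e), e3)
  expect_equal(ev_type(varied_end(300), varied_end(320), "+"), "A5")
  expect_equal(ev_type(varied_end(300), varied_end(320), "-"), "A3")
})

test_that("terminal-exon skips are AF/AL, not SE, and strand-aware", {
  e1 <- c(0, 100); e2 <- c(200, 300); e3 <- c(400, 500)
  expect_equal(ev_type(rbind(e1, e2, e3), rbind(e2, e3), "+"), "AF")
  expect_equal(ev_type(rbind(e1, e2, e3), rbind(e2, e3), "-"), "AL")
  expect_equal(ev_type(rbind(e1, e2, e3), rbind(e1, e2), "+"), "AL")
  expect_equal(ev_type(rbind(e1, e2, e3), rbind(e1, e2), "-"), "AF")
})

test_that("classification errors on mismatched gene, chrom or strand", {
  a <- make_tm(rbind(c(0, 10)), gene = "g1")
  b <- transcript_model("g2", "t2", "chr1", "+", rbind(c(0, 10)))
  expect_error(classify_event(a, b), "different genes")
  c2 <- transcript_model("g1", "t2", "chr2", "+", rbind(c(0, 10)))
  expect_error(classify_event(a, c2), "chromosomes or strands")
})

test_that("classification is symmetric in argument order", {
  chains <- enumerate_chains(6L, 3L)
  withr::local_seed(21)
  idx <- cbind(sample(length(chains), 120, TRUE),
               sample(length(chains), 120, TRUE))
  for (s in c("+", "-"))
    for (r in seq_len(nrow(idx))) {
      A <- chains[[idx[r, 1]]]; B <- chains[[idx[r, 2]]]
      ab <- classify_event(make_tm(A, s, tx = "a"), make_tm(B, s, tx = "b"))
      ba <- classify_event(make_tm(B, s, tx = "b"), make_tm(A, s, tx = "a"))
      expect_identical(ab$event_type, ba$event_type)
      if (!is.null(ab$event_coords))
        expect_setequal(
          apply(ab$event_coords, 1, paste, collapse = "-"),
          apply(ba$event_coords, 1, paste, collapse = "-"))
    }
})

test_that("exhaustive grid: classifier agrees with the independent checker", {
  # every chain of up to 4 exons drawn from an 8-boundary grid, both strands
  chains <- enumerate_chains(8L, 4L)
  counts <- c(identical = 0, SE = 0, RI = 0, A3 = 0, A5 = 0, AF = 0,
              AL = 0, MX = 0, complex = 0)
  mismatches <- character()
  for (s in c("+", "-"))
    for (A in chains)
      for (B in chains) {
        got <- classify_event(make_tm(A, s, tx = "a"),
                              make_tm(B, s, tx = "b"))$event_type
        want <- oracle_classify(A, B, s)
        if (!identical(got, want))
          mismatches <- c(mismatches,
                          sprintf("(%s) got %s oracle %s A=%s B=%s", s, got,
                                  want, paste(t(A), collapse = ","),
                                  paste(t(B), collapse = ",")))
        counts[got] <- counts[got] + 1
      }
  expect_identical(mismatches, character())
  # every event type is actually exercised by the grid
  expect_true(all(counts > 0))
})

test_that("strand involution: flipping strand swaps A3/A5 and AF/AL; mirroring too preserves labels", {
  chains <- enumerate_chains(6L, 3L)
  swap <- c(identical = "identical", SE = "SE", RI = "RI", A3 = "A5",
            A5 = "A3", AF = "AL", AL = "AF", MX = "MX", complex = "complex")
  mirror <- function(X) {
    M <- cbind(1000 - X[, 2L], 1000 - X[, 1L])
    M[order(M[, 1L]), , drop = FALSE]
  }
  withr::local_seed(33)
  idx <- cbind(sample(length(chains), 150, TRUE),
               sample(length(chains), 150, TRUE))
  for (r in seq_len(nrow(idx))) {
    A <- chains[[idx[r, 1]]]; B <- chains[[idx[r, 2]]]
    plus <- ev_type(A, B, "+")
    # same coordinates, opposite strand: labels swap sides
    expect_identical(ev_type(A, B, "-"), unname(swap[plus]))
    # mirrored coordinates AND flipped strand: same transcript read in the
    # same transcription order, so every label is preserved
    expect_identical(ev_type(mirror(A), mirror(B), "-"), plus)
  }
})

test_that("event tables report 1-based inclusive genomic coordinates", {
  models <- list(
    a = transcript_model("g", "a", "c", "+",
                         rbind(c(0, 100), c(200, 300), c(400, 500))),
    b = transcript_model("g", "b", "c", "+", rbind(c(0, 100), c(400, 500))))
  tab <- classify_event_table(models,
                              data.frame(isoform_a = "a", isoform_b = "b"))
  expect_equal(tab$event_type, "SE")
  expect_equal(tab$coords_1based, "201-300")
})
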