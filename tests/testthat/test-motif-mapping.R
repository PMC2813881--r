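make_calls <- function(pos, dir = rep("protection", length(pos))) {
  out <- tibble::tibble(position = as.integer(pos), direction = dir,
                        delta = ifelse(dir == "protection", -0.4, 0.4),
                        magnitude = 0.4)
  class(out) <- c("change_calls", class(tibble::tibble()))
  out
}

test_that("GNRA tetraloop detection matches the G-N-R-A pattern definition", {
  gnra <- function(loop) {
    # 4 bp stem closed hairpin with the given 4-nt loop
    parse_dotbracket(paste0("GGGC", loop, "GCCC"), "((((....))))")
  }
  expect_equal(nrow(find_gnra_tetraloops(gnra("GAAA"))), 1L)
  expect_equal(nrow(find_gnra_tetraloops(gnra("GCGA"))), 1L)  # N=C, R=G
  expect_equal(nrow(find_gnra_tetraloops(gnra("GUGA"))), 1L)
  expect_equal(nrow(find_gnra_tetraloops(gnra("UUCG"))), 0L)
  expect_equal(nrow(find_gnra_tetraloops(gnra("GAAC"))), 0L)  # must end in A
  expect_equal(nrow(find_gnra_tetraloops(gnra("GACA"))), 0L)  # R must be purine
  # loops of the wrong size never match
  five <- parse_dotbracket("GGGCGAAAAGCCC", "((((.....))))")
  expect_equal(nrow(find_gnra_tetraloops(five)), 0L)
})

test_that("GNRA scan agrees with a brute-force window scan on toy models", {
  for (seed in 1:5) {
    m <- toy_model(200, seed = seed)
    partner <- integer(m$length)
    partner[m$pairs$i] <- m$pairs$j
    partner[m$pairs$j] <- m$pairs$i
    # brute force: every 4-wide window of unpaired nucleotides closed by a pair
    brute <- c()
    for (s in 1:(m$length - 3)) {
      w <- s:(s + 3)
      if (any(partner[w] != 0)) next
      if (s == 1 || s + 4 > m$length) next
      if (partner[s - 1] != s + 4) next
      sq <- m$sequence[w]
      if (sq[1] == "G" && sq[3] %in% c("A", "G") && sq[4] == "A") brute <- c(brute, s)
    }
    expect_equal(find_gnra_tetraloops(m)$start, brute)
  }
})

test_that("call assignment classifies within/adjacent/distal by distance to contact elements", {
  m <- toy_model(200, seed = 2)
  receptor <- element_positions(m, "P8")
  inside <- receptor[3]
  outside2 <- max(receptor) + 2L   # 2 nt outside the receptor helix
  a2 <- assign_calls(make_calls(c(inside, outside2)), m, adjacency_k = 2)
  expect_equal(a2$adjacency, c("within", "adjacent"))
  expect_equal(a2$element[1], "P8")
  a1 <- assign_calls(make_calls(outside2), m, adjacency_k = 1)
  expect_equal(a1$adjacency, "distal")
  # the tetraloop itself is a contact element
  expect_equal(assign_calls(make_calls(element_positions(m, "L2")[1]), m)$adjacency,
               "within")
  expect_error(assign_calls(make_calls(10 * m$length), m), "outside")
})

test_that("element summaries count calls and satisfy the counting invariant", {
  m <- toy_model(200, seed = 2)
  prot <- element_positions(m, "L2")
  enh <- element_positions(m, "P4")[1:2]
  calls <- make_calls(c(prot, enh),
                      c(rep("protection", length(prot)), rep("enhancement", 2)))
  sm <- summarize_elements(assign_calls(calls, m), m)
  expect_true(all(sm$n_protected + sm$n_enhanced <= sm$n_positions))
  expect_equal(sm$n_protected[sm$label == "L2"], 4L)
  expect_equal(sm$n_enhanced[sm$label == "P4"], 2L)
  expect_true(all(sm$in_tetraloop_receptor[sm$label %in% c("L2", "P8", "L9", "P5")]))
  expect_false(any(sm$in_tetraloop_receptor[sm$label %in% c("P4", "P6", "J1")]))
})

test_that("motif coverage counts within/adjacent protections and flags the no-call case", {
  m <- toy_model(200, seed = 3)
  # all protections inside contact elements -> coverage exactly 1
  calls <- make_calls(c(element_positions(m, "L2"), element_positions(m, "P5")))
  expect_equal(motif_coverage(assign_calls(calls, m)), 1.0)
  # half inside, half far away in a junction
  far <- element_positions(m, "J4")
  far <- far[ceiling(length(far) / 2)]
  mixed <- make_calls(c(element_positions(m, "L2"), rep(far, 4)))
  expect_equal(motif_coverage(assign_calls(mixed, m)), 0.5)
  # enhancements do not count toward protection coverage
  enh_only <- make_calls(far, "enhancement")
  expect_warning(cov <- motif_coverage(assign_calls(enh_only, m)), "undefined")
  expect_true(is.na(cov))
  expect_true(attr(cov, "undefined"))
})

test_that("motif coverage is monotone non-decreasing in the adjacency distance", {
  m <- toy_model(300, seed = 6)
  set.seed(99)
  calls <- make_calls(sort(sample(m$length, 40)))
  covs <- vapply(0:6, function(k) motif_coverage(assign_calls(calls, m, k)),
                 numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("three-part signature reports loop, receptor and extension segments per motif", {
  m <- toy_model(200, seed = 4)
  ct <- m$contacts
  all3 <- make_calls(c(ct$loop_positions[[1]], ct$receptor_positions[[1]],
                       ct$extension_positions[[1]]))
  rep1 <- signature_check(all3, m)
  expect_true(rep1$complete[rep1$loop == "L2"])
  expect_false(rep1$complete[rep1$loop == "L9"])
  # loop-only footprint
  loop_only <- signature_check(make_calls(ct$loop_positions[[1]]), m)
  expect_equal(unlist(loop_only[loop_only$loop == "L2",
                                c("loop_protected", "receptor_protected",
                                  "extension_protected")]),
               c(loop_protected = TRUE, receptor_protected = FALSE,
                 extension_protected = FALSE))
})

test_that("simulated bound-vs-free assignments match the generator footprint placement", {
  run <- run_pipeline(config = simulation_config(length = 300, seed = 17))
  truth <- sort(unique(unlist(c(run$model$contacts$loop_positions,
                                run$model$contacts$receptor_positions,
                                run$model$contacts$extension_positions))))
  prot <- run$assignments[run$assignments$direction == "protection", ]
  # every true footprint position is recovered as a protection call
  expect_true(all(truth %in% prot$position))
  # and protections stay within/adjacent to the motifs
  expect_true(all(prot$adjacency %in% c("within", "adjacent")))
  expect_true(all(run$signatures$complete))
})
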