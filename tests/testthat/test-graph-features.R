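test_that("autocorrelation matches hand-computed small-molecule values", {
  w <- water_graph()
  # depth-0 identity product counts the atoms
  expect_equal(autocorrelation(w, 1:3, "product", "I", 0), 3)
  # depth-0 differences vanish identically
  for (p in c("Z", "chi", "T")) {
    expect_equal(autocorrelation(w, 1:3, "difference", p, 0), 0)
  }
  # water depth-1 product over Z: ordered pairs (H,O),(O,H),(O,H),(H,O)
  expect_equal(autocorrelation(w, 1:3, "product", "Z", 1), 32)
  # depth beyond the graph diameter contributes nothing
  expect_equal(autocorrelation(w, 1:3, "product", "Z", 5), 0)
  # undefined element errors by name
  g <- molecular_graph(c("Xx", "C"), rbind(c(1, 2)))
  expect_error(autocorrelation(g, 1:2, "product", "Z", 0), "Xx")
})

test_that("autocorrelation equals the brute-force ordered-pair oracle", {
  set.seed(42)
  for (rep in 1:200) {
    g <- random_molgraph(8)
    p <- sample(c("I", "Z", "chi", "T", "S", "G", "NB"), 1)
    op <- sample(c("product", "difference"), 1)
    d <- sample(0:3, 1)
    start <- sample(seq_along(g$elements),
                    sample(seq_along(g$elements), 1))
    expect_equal(autocorrelation(g, start, op, p, d),
                 oracle_autocorrelation(g, start, op, p, d))
  }
})

test_that("feature values are invariant to atom relabeling", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_molgraph(7)
    n <- length(g$elements)
    perm <- sample(n)
    # permuted graph: atom i of g sits at position perm[i] of g2
    els <- character(n); els[perm] <- g$elements
    g2 <- molecular_graph(els, cbind(perm[g$bonds[, 1]], perm[g$bonds[, 2]]))
    expect_equal(autocorrelation(g2, perm, "product", "Z", 2),
                 autocorrelation(g, seq_len(n), "product", "Z", 2))
  }
})

test_that("identity-property products count ordered pairs at each depth", {
  set.seed(5)
  g <- random_molgraph(8)
  D <- oracle_distances(g$elements, g$bonds)
  for (d in 0:3) {
    expect_equal(autocorrelation(g, seq_along(g$elements), "product", "I", d),
                 sum(D == d))
  }
})

test_that("ligand-only RACs have the documented block structure", {
  cn <- toy_cn_ligand(); nn <- toy_nn_ligand()
  v <- ligand_racs(cn, nn)
  expect_length(v, 70)
  expect_length(ligand_racs(cn, nn, d_max = 0), 14)
  # depth-0 identity entries equal each ligand's atom count
  expect_equal(unname(v["cn_prod_I_d0"]), length(cn$graph$elements))
  expect_equal(unname(v["nn_prod_I_d0"]), length(nn$graph$elements))
  # CN block strictly precedes NN block
  expect_true(all(startsWith(names(v)[1:35], "cn_")))
  expect_true(all(startsWith(names(v)[36:70], "nn_")))
})

test_that("whole-complex RACs have 196 features with stable names", {
  cx <- assemble_complex(toy_cn_ligand(), toy_nn_ligand())
  v <- complex_racs(cx)
  expect_length(v, 196)
  expect_identical(anyDuplicated(names(v)), 0L)
  # metal-centered depth-0 difference vanishes for every property
  d0diff <- v[grepl("^mc_diff_.*_d0$", names(v))]
  expect_length(d0diff, 7)
  expect_true(all(d0diff == 0))
  # metal-centered depth-0 Z product is the Ir self-pair 77^2
  expect_equal(unname(v["mc_prod_Z_d0"]), 77^2)
  # byte-identical names across repeated calls and across complexes
  cx2 <- assemble_complex(small_library(1, 1, 3)$cn[[1]],
                          small_library(1, 1, 3)$nn[[1]])
  expect_identical(names(complex_racs(cx2)), names(v))
})

test_that("CD-RACs encode 1/r decay with 222 features", {
  cx <- assemble_complex(toy_cn_ligand(), toy_nn_ligand(), embed = TRUE)
  v <- cd_racs(cx)
  expect_length(v, 222)
  # doubling all coordinates halves every depth >= 1 product term
  cx2 <- cx
  cx2$whole_graph$coords <- cx$whole_graph$coords * 2
  v2 <- cd_racs(cx2)
  d1plus <- grepl("prod_.*_d[123]_cd$", names(v))
  expect_equal(v2[d1plus], v[d1plus] / 2)
  # depth-0 products keep the undecayed atomic self-terms
  d0 <- grepl("prod_.*_d0_cd$", names(v))
  expect_equal(v2[d0], v[d0])
  # two-atom toy at 1 Angstrom: depth-1 Z product = 2 * (1 * 8) / 1
  g <- molecular_graph(c("H", "O"), rbind(c(1, 2)),
                       coords = rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(autocorrelation(g, 1:2, "product", "Z", 1, decay = TRUE), 16)
  # with all pairwise distances 1, CD equals the plain AC for d >= 1
  expect_equal(autocorrelation(g, 1:2, "product", "Z", 1, decay = TRUE),
               autocorrelation(g, 1:2, "product", "Z", 1))
  # missing coordinates error
  expect_error(cd_racs(assemble_complex(toy_cn_ligand(), toy_nn_ligand())),
               "coordinates")
})

test_that("axial/equatorial plane weights normalize within each class", {
  cx <- assemble_complex(toy_cn_ligand(), toy_nn_ligand())
  pl <- assign_ligand_planes(cx)
  expect_equal(sum(pl$ax_weight), 1)
  expect_equal(sum(pl$eq_weight), 1)
  # the NN ligand is purely equatorial; CN ligands sit in both classes
  expect_equal(pl$ax_weight[pl$role == "NN"], 0)
  expect_true(all(pl$ax_weight[pl$role == "CN"] > 0))
  expect_true(all(pl$eq_weight[pl$role == "CN"] > 0))
})
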