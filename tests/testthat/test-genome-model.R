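test_that("starting genome has one default-strength promoter upstream of gene 1", {
  g <- make_starting_genome(3)
  expect_s3_class(g, "genome_architecture")
  expect_equal(n_genes(g), 3)
  expect_equal(g$genes$length, rep(150L, 3))
  expect_equal(nrow(g$elements), 1)
  expect_equal(g$elements$kind, "promoter")
  expect_equal(g$elements$region, 0L)
  expect_equal(g$elements$strength, 1e6)

  g1 <- make_starting_genome(1)
  expect_equal(n_genes(g1), 1)
  expect_equal(nrow(genome_coordinates(g1)$regions), 2)  # M + 1 regions

  g10 <- make_starting_genome(10)
  expect_equal(nrow(genome_coordinates(g10)$regions), 11)
  expect_error(make_starting_genome(0), "n_genes")
})

test_that("genome coordinates are 1-based, contiguous and non-overlapping", {
  g <- make_starting_genome(3)
  co <- genome_coordinates(g)
  expect_equal(co$regions$start[1], 1L)
  expect_equal(co$genes$start, c(51L, 251L, 451L))
  expect_equal(co$genes$end, c(200L, 400L, 600L))
  expect_equal(genome_length(g), 650L)
  # genes strictly ordered, no overlap with each other or the spacers
  expect_true(all(diff(co$genes$start) > 0))
  expect_true(all(co$genes$start[-1] > co$genes$end[-3]))
  # element point positions fall inside their region, in 5'->3' kind order
  full <- positive_control_genome()
  ep <- element_positions(full)
  reg <- genome_coordinates(full)$regions
  for (i in seq_len(nrow(ep))) {
    r <- reg[reg$region == ep$region[i], ]
    expect_true(ep$position[i] >= r$start && ep$position[i] <= r$end)
  }
  r1 <- ep[ep$region == 1, ]
  expect_lt(r1$position[r1$kind == "promoter"],
            r1$position[r1$kind == "rnase_site"])
})

test_that("architecture invariants are enforced", {
  expect_error(genome_architecture(data.frame(name = "a", length = 0)),
               "positive")
  expect_error(
    genome_architecture(data.frame(name = c("a", "a"), length = 150)),
    "unique")
  expect_error(add_element(make_starting_genome(3), "promoter", 0L),
               "duplicate")
  expect_error(add_element(make_starting_genome(3), "promoter", 5L),
               "out of range")
  expect_error(add_element(make_starting_genome(3), "promoter", 1L, 1e4),
               "bounds")
  expect_error(add_element(make_starting_genome(3), "terminator", 1L, 1.5),
               "bounds")
})

test_that("fingerprints ignore strengths and distinguish element placement", {
  a <- positive_control_genome()
  b <- set_element_strength(a, "promoter", 0L, 5e7)
  b <- set_element_strength(b, "terminator", 2L, 0.9)
  expect_identical(fingerprint(a), fingerprint(b))

  moved <- add_element(remove_element(a, "terminator", 2L), "terminator", 0L)
  expect_false(identical(fingerprint(a), fingerprint(moved)))

  bare <- genome_architecture(data.frame(name = "g1", length = 150))
  expect_identical(fingerprint(bare), "")

  # canonical: construction order does not matter
  el <- a$elements[rev(seq_len(nrow(a$elements))), ]
  a2 <- genome_architecture(a$genes, el)
  expect_identical(fingerprint(a), fingerprint(a2))
})

test_that("architecture files round-trip through YAML and JSON", {
  g <- positive_control_genome()
  for (ext in c(".yaml", ".json")) {
    path <- temp_path(ext)
    write_architecture(g, path)
    expect_equal(read_architecture(path), g)
    # bit-stable serialization
    path2 <- temp_path(ext)
    write_architecture(g, path2)
    expect_identical(readLines(path), readLines(path2))
    unlink(c(path, path2))
  }
})

test_that("schema violations in architecture files are rejected by name", {
  path <- temp_path(".yaml")
  yaml::write_yaml(list(
    genes = list(list(name = "g1", length = 150),
                 list(name = "g2", length = 150),
                 list(name = "g3", length = 150)),
    elements = list(list(kind = "terminator", region = 2, strength = 0.2),
                    list(kind = "terminator", region = 2, strength = 0.5)),
    spacer_length = 50
  ), path)
  expect_error(read_architecture(path), "terminator 2")

  yaml::write_yaml(list(
    genes = list(list(name = "g1", length = 150)),
    elements = list(list(kind = "promoter", region = 0, strength = 1e4)),
    spacer_length = 50
  ), path)
  expect_error(read_architecture(path), "bounds")
  unlink(path)
})
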