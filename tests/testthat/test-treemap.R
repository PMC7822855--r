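leaves_of <- function(node) {
  if (!length(node$children)) return(list(node))
  do.call(c, lapply(node$children, leaves_of))
}

rect_overlap <- function(a, b) {
  max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])) *
    max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
}

test_that("hierarchy frequencies nest and conserve", {
  clon <- data.frame(v_gene = c("V1", "V1"), j_gene = c("J1", "J2"),
                     cdr3_nt = c("AAA", "CCC"), cdr3_aa = NA,
                     total_copies = c(3L, 1L), n_unique = 1L,
                     stringsAsFactors = FALSE)
  root <- build_hierarchy(clon)
  expect_equal(root$frequency, 1)
  expect_length(root$children, 1)
  v1 <- root$children[[1]]
  expect_equal(v1$frequency, 1)
  expect_equal(sort(vapply(v1$children, `[[`, numeric(1), "frequency")),
               c(0.25, 0.75))
  expect_equal(sum(vapply(leaves_of(root), `[[`, numeric(1), "frequency")),
               1, tolerance = 1e-9)
  expect_error(build_hierarchy(clon[0, ]), "empty")
})

test_that("layout satisfies area, overlap and proportionality invariants", {
  set.seed(41)
  for (t in 1:25) {
    clon <- random_clonotypes(sample(2:40, 1))
    root <- layout_treemap(build_hierarchy(clon), width = 600, height = 400,
                           seed = t)
    lv <- leaves_of(root)
    areas <- vapply(lv, function(x) x$rect[3] * x$rect[4], numeric(1))
    freqs <- vapply(lv, `[[`, numeric(1), "frequency")
    expect_equal(sum(areas), 600 * 400, tolerance = 1e-6 * 600 * 400)
    expect_equal(areas, freqs * 600 * 400, tolerance = 1e-6)
    # no two leaves overlap (leaves tile the canvas)
    if (length(lv) <= 15) {
      for (i in seq_along(lv)) for (j in seq_len(i - 1))
        expect_lt(rect_overlap(lv[[i]]$rect, lv[[j]]$rect), 1e-9)
    }
    # every leaf sits inside the canvas
    for (x in lv) {
      expect_gte(x$rect[1], -1e-9); expect_gte(x$rect[2], -1e-9)
      expect_lte(x$rect[1] + x$rect[3], 600 + 1e-9)
      expect_lte(x$rect[2] + x$rect[4], 400 + 1e-9)
    }
  }
})

test_that("single leaf fills the canvas; two leaves split proportionally", {
  clon1 <- random_clonotypes(1)
  root1 <- layout_treemap(build_hierarchy(clon1), 100, 100, seed = 1)
  leaf <- leaves_of(root1)[[1]]
  expect_equal(leaf$rect, c(0, 0, 100, 100))

  clon2 <- data.frame(v_gene = c("V1", "V2"), j_gene = "J1",
                      cdr3_nt = c("AAA", "CCC"), cdr3_aa = NA,
                      total_copies = c(3L, 1L), n_unique = 1L,
                      stringsAsFactors = FALSE)
  root2 <- layout_treemap(build_hierarchy(clon2), 100, 100, seed = 1)
  areas <- sort(vapply(leaves_of(root2), function(x) x$rect[3] * x$rect[4],
                       numeric(1)))
  expect_equal(areas, c(2500, 7500), tolerance = 1e-6)
})

test_that("the largest sibling sits at the bottom right", {
  clon <- random_clonotypes(12)
  root <- layout_treemap(build_hierarchy(clon), 600, 400, seed = 3)
  kids <- root$children
  freqs <- vapply(kids, `[[`, numeric(1), "frequency")
  big <- kids[[which.max(freqs)]]$rect
  # the biggest V rectangle touches the bottom-right corner of the canvas
  expect_equal(big[1] + big[3], 600, tolerance = 1e-6)
  expect_equal(big[2] + big[4], 400, tolerance = 1e-6)
})

test_that("layout and rendering are deterministic under a fixed seed", {
  clon <- random_clonotypes(10)
  r1 <- layout_treemap(build_hierarchy(clon), 300, 200, seed = 9)
  r2 <- layout_treemap(build_hierarchy(clon), 300, 200, seed = 9)
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  render_svg(r1, p1); render_svg(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  r3 <- layout_treemap(build_hierarchy(clon), 300, 200, seed = 10)
  expect_false(identical(vapply(leaves_of(r1), `[[`, character(1), "color"),
                         vapply(leaves_of(r3), `[[`, character(1), "color")))
})

test_that("SVG output is valid and has one rounded rect per CDR3", {
  clon <- random_clonotypes(3)
  clon$cdr3_nt <- c("AAA", "CCC", "GGG")  # force 3 distinct leaves
  root <- layout_treemap(build_hierarchy(clon), 300, 200, seed = 2)
  path <- withr::local_tempfile(fileext = ".svg")
  render_svg(root, path, corner_radius = 3)
  doc <- xml2::read_xml(path)
  rects <- xml2::xml_find_all(doc, "//*[local-name()='rect']")
  leaf_rects <- rects[xml2::xml_attr(rects, "class") == "leaf"]
  expect_length(leaf_rects, 3)
  expect_true(all(xml2::xml_attr(leaf_rects, "rx") == "3.0000"))

  render_svg(root, path, corner_radius = 0)
  doc0 <- xml2::read_xml(path)
  rects0 <- xml2::xml_find_all(doc0, "//*[local-name()='rect']")
  leaf0 <- rects0[xml2::xml_attr(rects0, "class") == "leaf"]
  expect_true(all(xml2::xml_attr(leaf0, "rx") == "0.0000"))
})
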