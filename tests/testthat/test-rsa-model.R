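test_that("a minimal one-segment system reads back with unit length", {
  f <- withr::local_tempfile(fileext = ".rsml")
  rs <- root_system(list(root("r1", rbind(c(0, 0, 0), c(0, 0, 1)),
                              diameters = 0.1)))
  write_rsml(rs, f)
  got <- read_rsml(f)
  expect_length(got$roots, 1L)
  segs <- to_segments(got)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$length, 1)
  expect_equal(got$roots[[1]]$diameters, c(0.1, 0.1))
})

test_that("RSML round-trip is lossless for geometry, diameters, order and parentage", {
  set.seed(11)
  rsa <- generate_root_system(generator_params(seed = 11))
  f <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(rsa, f)
  got <- read_rsml(f)
  expect_equal(root_ids(got), root_ids(rsa))
  for (i in seq_along(rsa$roots)) {
    a <- rsa$roots[[i]]; b <- got$roots[[i]]
    expect_lt(max(abs(a$nodes - b$nodes)), 1e-6)
    expect_lt(max(abs(a$diameters - b$diameters)), 1e-6)
    expect_identical(a$order, b$order)
    expect_identical(a$parent_root_id, b$parent_root_id)
    if (!is.null(a$parent_attachment))
      expect_equal(b$parent_attachment, a$parent_attachment, tolerance = 1e-6)
  }
})

test_that("nested child roots get order from nesting depth and resolve parents", {
  f <- withr::local_tempfile(fileext = ".rsml")
  writeLines(c(
    "<rsml><metadata><unit>cm</unit></metadata><scene><plant>",
    "<root ID='tap'><geometry><polyline>",
    "<point x='0' y='0' z='0'/><point x='0' y='0' z='5'/>",
    "</polyline></geometry>",
    "<root ID='child'><geometry><polyline>",
    "<point x='0' y='0' z='2'/><point x='1' y='0' z='2'/>",
    "</polyline></geometry></root>",
    "</root></plant></scene></rsml>"), f)
  got <- read_rsml(f)
  child <- got$roots[[2]]
  expect_identical(child$order, 1L)
  expect_identical(child$parent_root_id, "tap")
  expect_identical(got$roots[[1]]$order, 0L)
})

test_that("metadata unit and resolution rescale coordinates to cm", {
  f <- withr::local_tempfile(fileext = ".rsml")
  writeLines(c(
    "<rsml><metadata><unit>mm</unit><resolution>2</resolution></metadata>",
    "<scene><plant><root ID='r'><geometry><polyline>",
    "<point x='0' y='0' z='0'/><point x='0' y='0' z='10'/>",
    "</polyline></geometry></root></plant></scene></rsml>"), f)
  got <- read_rsml(f)
  # 10 units * resolution 2 * 0.1 cm/mm = 2 cm
  expect_equal(to_segments(got)$length, 2)
})

test_that("an empty system writes valid RSML with zero plants and reads back empty", {
  f <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(root_system(), f)
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, ".//plant"), 0L)
  expect_length(read_rsml(f)$roots, 0L)
})

test_that("a 26-root system is written as 26 root elements, 25 nested", {
  rsa <- generate_root_system(generator_params(seed = 3))
  f <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(rsa, f)
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, ".//root"), 26L)
  expect_length(xml2::xml_find_all(doc, ".//root/root"), 25L)
})

test_that("malformed and invalid files raise classed errors", {
  f <- withr::local_tempfile(fileext = ".rsml")
  writeLines("<rsml><scene>", f)
  expect_error(read_rsml(f), class = "rsaeval_parse_error")
  writeLines(c("<rsml><scene><plant><root ID='r'><geometry><polyline>",
               "<point x='0' y='0' z='0'/>",
               "</polyline></geometry></root></plant></scene></rsml>"), f)
  expect_error(read_rsml(f), class = "rsaeval_validation_error")
})

test_that("validation rejects broken systems and reports issues as data", {
  bad_parent <- root_system(list(
    straight_root("a", c(0, 0, 0), c(0, 0, 1), order = 1L, parent = "ghost")),
    validate = FALSE)
  expect_error(validate_root_system(bad_parent),
               class = "rsaeval_validation_error")
  rep <- validate_root_system(bad_parent, as_report = TRUE)
  expect_false(rep$valid)
  expect_match(unlist(rep$issues), "ghost", all = FALSE)

  dup_node <- root_system(list(
    root("a", rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)))), validate = FALSE)
  expect_error(validate_root_system(dup_node),
               class = "rsaeval_validation_error")
})

test_that("to_segments: counts, ordering, and length totals", {
  three <- root_system(list(
    root("r", rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)))))
  segs <- to_segments(three)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$length, c(1, 1))

  expect_equal(nrow(to_segments(root_system())), 0L)

  set.seed(21)
  rsa <- random_small_rsa(4L)
  segs <- to_segments(rsa)
  # segment count per root = node count - 1
  per_root <- table(factor(segs$root_id, levels = root_ids(rsa)))
  nodes_per_root <- vapply(rsa$roots, function(r) nrow(r$nodes), integer(1))
  expect_equal(as.integer(per_root), nodes_per_root - 1L)
  # direct summation oracle for total length
  expect_equal(sum(segs$length), total_length(rsa), tolerance = 1e-9)
  # deterministic and order-stable
  expect_identical(segs, to_segments(rsa))
})
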