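svg_doc_of <- function(svg) xml2::read_xml(svg)

svg_nodes <- function(svg, xpath) {
  doc <- xml2::read_xml(svg)
  xml2::xml_ns_strip(doc)
  xml2::xml_find_all(doc, xpath)
}

test_that("a two-taxon tree renders two tip labels spanning the time axis", {
  tr <- validate_tree(ape::read.tree(text = "(A:1,B:1);"))
  svg <- render_tree_svg(tr)
  tips <- svg_nodes(svg, "//text[@class='tip']")
  expect_length(tips, 2)
  expect_setequal(xml2::xml_text(tips), c("A", "B"))
  paths <- svg_nodes(svg, "//path")
  xs <- unlist(lapply(xml2::xml_attr(paths, "d"), function(d)
    as.numeric(regmatches(d, gregexpr("-?[0-9.]+", d))[[1]][c(1, 3, 5)])))
  # left margin 60, width 800, right margin 20: edges span [60, 780]
  expect_equal(min(xs), 60, tolerance = 1e-6)
  expect_equal(max(xs), 780, tolerance = 1e-6)
})

test_that("rendering is byte-stable across runs", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 181)
  rates <- tibble::tibble(locus = "L", site = 1:5, rate = 1,
                          status = "OK", loglik = NA_real_, model = "JC69")
  prof <- pi_profile(rates, depth = 1, n_grid = 50)
  expect_identical(render_tree_svg(tr), render_tree_svg(tr))
  expect_identical(render_figure(tr, prof), render_figure(tr, prof))
})

test_that("all tips align at the present on the time axis", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 191)
  svg <- render_tree_svg(tr)
  tips <- svg_nodes(svg, "//text[@class='tip']")
  xs <- as.numeric(xml2::xml_attr(tips, "x"))
  expect_length(xs, 8)
  expect_lt(max(xs) - min(xs), 0.5)
})

test_that("SVG output is well-formed XML with shared x-transform panels", {
  tr <- sim_ultrametric_tree(6, depth = 1, seed = 201)
  rates <- tibble::tibble(locus = "L", site = 1:10, rate = 1,
                          status = "OK", loglik = NA_real_, model = "JC69")
  prof <- pi_profile(rates, depth = 1, n_grid = 200)
  svg <- render_figure(tr, prof)
  expect_silent(doc <- svg_doc_of(svg))   # parse failure would error
  # tree tips sit at t = 0; the profile polyline starts at t = 0 too:
  # both must map to the same x coordinate
  tips <- svg_nodes(svg, "//text[@class='tip']")
  tip_x <- max(as.numeric(xml2::xml_attr(tips, "x"))) - 4  # label offset
  poly <- svg_nodes(svg, "//polyline[@class='locus']")
  pts <- strsplit(xml2::xml_attr(poly[[1]], "points"), " ")[[1]]
  first_x <- as.numeric(strsplit(pts[1], ",")[[1]][1])
  expect_equal(tip_x, first_x, tolerance = 1e-6)
})

test_that("the profile peak lands at the expected time coordinate", {
  rates <- tibble::tibble(locus = "L", site = 1L, rate = 1,
                          status = "OK", loglik = NA_real_, model = "JC69")
  prof <- pi_profile(rates, depth = 1, n_grid = 2001)
  svg <- render_profiles_svg(prof)
  poly <- svg_nodes(svg, "//polyline[@class='locus']")
  pts <- do.call(rbind, lapply(strsplit(
    strsplit(xml2::xml_attr(poly[[1]], "points"), " ")[[1]], ","),
    as.numeric))
  # invert the linear x-transform: x = 60 + t / depth * 720
  t_peak <- (pts[which.min(pts[, 2]), 1] - 60) / 720  # min y = max value
  expect_equal(t_peak, 0.25, tolerance = 0.01)
})

test_that("loci are drawn with their requested colors", {
  rates <- dplyr::bind_rows(
    tibble::tibble(locus = "L1", site = 1:3, rate = 0.5, status = "OK",
                   loglik = NA_real_, model = "JC69"),
    tibble::tibble(locus = "L2", site = 1:3, rate = 2, status = "OK",
                   loglik = NA_real_, model = "JC69"))
  prof <- pi_profile(rates, depth = 1, n_grid = 40)
  spec <- plot_spec(colors = c(L1 = "#112233", L2 = "#AABBCC"))
  svg <- render_profiles_svg(prof, spec)
  poly <- svg_nodes(svg, "//polyline[@class='locus']")
  expect_length(poly, 2)
  expect_setequal(xml2::xml_attr(poly, "stroke"), c("#112233", "#AABBCC"))
})

test_that("invalid plot requests error clearly", {
  rates <- tibble::tibble(locus = "L", site = 1:3, rate = 1,
                          status = "OK", loglik = NA_real_, model = "JC69")
  prof <- pi_profile(rates, depth = 1, n_grid = 10)
  expect_error(render_profiles_svg(prof, loci = "missing"), "available")
  expect_error(plot_spec(time_window = c(1, 1)), "time_window")
  expect_error(plot_spec(colors = "blue"), "hex")
})

test_that("epoch shading and flipped time axes render", {
  tr <- sim_ultrametric_tree(5, depth = 1, seed = 211)
  rates <- tibble::tibble(locus = "L", site = 1:4, rate = 1,
                          status = "OK", loglik = NA_real_, model = "JC69")
  prof <- pi_profile(rates, depth = 1, n_grid = 30)
  spec <- plot_spec(epoch_shading = list(c(0.2, 0.5)), flip_time = TRUE)
  svg <- render_figure(tr, prof, spec)
  expect_length(svg_nodes(svg, "//rect[@class='epoch']"), 1)
})

test_that("autoplot methods return ggplot objects", {
  rates <- fast_slow_rates()
  prof <- pi_profile(rates, n_grid = 20)
  expect_s3_class(autoplot(prof), "ggplot")
  expect_s3_class(autoplot(rank_loci(rates, c(0, 1))), "ggplot")
})
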