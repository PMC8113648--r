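# Shared fixtures: scenarios are solved lazily and cached for the whole test
# run; meshes/factorisations are additionally cached inside the package, so
# scenarios sharing a discretisation are cheap.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

coarse_mesh <- function() mesh_spec(10, 30)

geom_default <- function() fixture("geom", junction_geometry)

layout_full <- function() fixture("layout_full", function()
  channel_layout(geom_default()))

layout_orai_only <- function() fixture("layout_orai_only", function()
  channel_layout(geom_default(), n_ip3r = 0))

# rest state: full layout, nothing open (coarse)
sol_rest <- function() fixture("sol_rest", function()
  solve_steady(scenario(geom_default(), layout_full(), mesh = coarse_mesh())))

# five ORAI1 at the full-ER fraction, no IP3Rs (coarse)
sol_orai5 <- function() fixture("sol_orai5", function()
  solve_steady(scenario(geom_default(), layout_orai_only(),
                        open_orai = 1:5, mesh = coarse_mesh())))

# one IP3R open, ORAIs gated, D_S = 10 (coarse)
sol_ip3r1 <- function() fixture("sol_ip3r1", function()
  solve_steady(scenario(geom_default(), layout_full(),
                        params = flux_params(D_S = 10),
                        open_orai = 1:5, open_ip3r = 1L,
                        orai_gated_by_sensing = TRUE, mesh = coarse_mesh())))

# same with fast ER diffusion (coarse)
sol_ip3r1_fast <- function() fixture("sol_ip3r1_fast", function()
  solve_steady(scenario(geom_default(), layout_full(),
                        params = flux_params(D_S = 110),
                        open_orai = 1:5, open_ip3r = 1L,
                        orai_gated_by_sensing = TRUE, mesh = coarse_mesh())))

# flat-PM verification geometry: a single ORAI1 on a large membrane, no ER
sol_flat <- function() fixture("sol_flat", function() {
  gf <- junction_geometry(box_side = 2000, gap = 15, junction_radius = 30,
                          cone_top_radius = 0, cone_bottom_radius = 0,
                          cone_depth = 985)
  lay <- channel_layout(gf, n_orai = 1, orai_ring_radius = 0,
                        n_serca = 0, n_ip3r = 0)
  solve_steady(scenario(gf, lay, open_orai = 1L, mesh = mesh_spec(6, 100)))
})

# default-resolution (production profile) solutions for quantitative anchors
sol_orai5_prod <- function() fixture("sol_orai5_prod", function()
  solve_steady(preset_scenario("fig2", n_open = 5)))

sol_orai1_prod <- function() fixture("sol_orai1_prod", function()
  solve_steady(preset_scenario("fig2", n_open = 1)))

sol_ip3r1_prod <- function() fixture("sol_ip3r1_prod", function()
  solve_steady(preset_scenario("fig3", n_open = 1)))

sol_ip3r1_fast_prod <- function() fixture("sol_ip3r1_fast_prod", function()
  solve_steady(preset_scenario("fig5", n_open = 1)))
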