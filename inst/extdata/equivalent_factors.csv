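# Per-unit-area ecosystem-service equivalents (dimensionless) for the six
# aggregate land-use classes and the 11 service functions, following the
# widely used China terrestrial equivalent scale. Aggregation choices:
# cultivated = dryland cropland row (dry-valley setting; the paddy water-supply
# equivalent is negative and is not applicable here); forest and grassland are
# arithmetic means of the published sub-type rows; construction is zero by
# convention; unused = bare-land row. Edit or replace via the valuation config.
class,food_production,raw_material,water_supply,gas_regulation,climate_regulation,environment_purification,water_regulation,soil_conservation,nutrient_cycling,biodiversity,aesthetic_landscape
cultivated,0.85,0.40,0.02,0.67,0.36,0.10,0.27,1.03,0.12,0.13,0.06
forest,0.25,0.58,0.30,1.91,5.71,1.67,3.74,2.32,0.18,2.12,0.93
grassland,0.19,0.28,0.15,0.98,2.59,0.85,1.89,1.19,0.09,1.08,0.48
water,0.80,0.23,8.29,0.77,2.29,5.55,102.24,0.93,0.07,2.55,1.89
construction,0,0,0,0,0,0,0,0,0,0,0
unused,0.00,0.00,0.00,0.02,0.00,0.10,0.03,0.02,0.00,0.02,0.01
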