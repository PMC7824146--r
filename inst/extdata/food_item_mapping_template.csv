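food_item,component
# Template food-item -> food-group mapping for map_food_items().
# One row per distinct food item in your survey; component must be one of the
# 13 ids below or EXCLUDED. Group definitions (summarised):
#   whole_grains - whole-grain rice/wheat/corn and whole-grain products
#                  (bran+germ+endosperm); refined grains are EXCLUDED
#   vegetables   - fresh/frozen/cooked/canned/dried vegetables; excludes
#                  legumes, pickled vegetables, juices, starchy vegetables
#   fruits       - fresh/frozen/cooked/canned/dried fruit; excludes juices,
#                  pickled fruit, nuts and seeds
#   dairy        - milk and derivatives (cheese, yoghurt, curd); excludes
#                  butter and cream
#   red_meat     - beef, pork, lamb, goat incl. processed forms
#   fish         - fish and shellfish (mussels, shrimp)
#   eggs         - chicken and duck eggs; excludes fish eggs
#   poultry      - chicken, duck, goose meat
#   legumes      - beans, lentils, peas, soy foods
#   nuts         - tree nuts and ground nuts incl. peanuts
#   unsat_oils   - olive, soybean, rapeseed, sunflower, peanut oil
#   sat_oils     - palm oil, dairy fats, lard, tallow
#   added_sugars - added sugar and sugar-sweetened beverages
# Tubers and starchy vegetables are EXCLUDED from the index by design.
white rice,EXCLUDED
brown rice,whole_grains
morning glory,vegetables
banana,fruits
yoghurt,dairy
pork,red_meat
beef,red_meat
tilapia,fish
chicken egg,eggs
chicken breast,poultry
tofu,legumes
peanut,nuts
soybean oil,unsat_oils
palm oil,sat_oils
sugar,added_sugars
cassava,EXCLUDED
fruit juice,EXCLUDED
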