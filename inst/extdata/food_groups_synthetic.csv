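item,group
cooked_rice_item01,cooked_rice
cooked_rice_item02,cooked_rice
cooked_rice_item03,cooked_rice
cooked_rice_item04,cooked_rice
mixed_grain_rice_item01,mixed_grain_rice
mixed_grain_rice_item02,mixed_grain_rice
mixed_grain_rice_item03,mixed_grain_rice
mixed_grain_rice_item04,mixed_grain_rice
noodles_item01,noodles
noodles_item02,noodles
noodles_item03,noodles
noodles_item04,noodles
breads_item01,breads
breads_item02,breads
breads_item03,breads
breads_item04,breads
cereals_item01,cereals
cereals_item02,cereals
cereals_item03,cereals
cereals_item04,cereals
rice_cakes_item01,rice_cakes
rice_cakes_item02,rice_cakes
rice_cakes_item03,rice_cakes
potatoes_item01,potatoes
potatoes_item02,potatoes
potatoes_item03,potatoes
potatoes_item04,potatoes
beans_item01,beans
beans_item02,beans
beans_item03,beans
tofu_soy_item01,tofu_soy
tofu_soy_item02,tofu_soy
tofu_soy_item03,tofu_soy
tofu_soy_item04,tofu_soy
nuts_item01,nuts
nuts_item02,nuts
nuts_item03,nuts
nuts_item04,nuts
green_vegetables_item01,green_vegetables
green_vegetables_item02,green_vegetables
green_vegetables_item03,green_vegetables
white_vegetables_item01,white_vegetables
white_vegetables_item02,white_vegetables
white_vegetables_item03,white_vegetables
white_vegetables_item04,white_vegetables
kimchi_item01,kimchi
kimchi_item02,kimchi
kimchi_item03,kimchi
pickles_item01,pickles
pickles_item02,pickles
pickles_item03,pickles
pickles_item04,pickles
mushrooms_item01,mushrooms
mushrooms_item02,mushrooms
mushrooms_item03,mushrooms
mushrooms_item04,mushrooms
seaweeds_item01,seaweeds
seaweeds_item02,seaweeds
seaweeds_item03,seaweeds
fruits_item01,fruits
fruits_item02,fruits
fruits_item03,fruits
fruits_item04,fruits
fruit_juices_item01,fruit_juices
fruit_juices_item02,fruit_juices
fruit_juices_item03,fruit_juices
fruit_juices_item04,fruit_juices
red_meat_item01,red_meat
red_meat_item02,red_meat
red_meat_item03,red_meat
red_meat_item04,red_meat
poultry_item01,poultry
poultry_item02,poultry
poultry_item03,poultry
processed_meat_item01,processed_meat
processed_meat_item02,processed_meat
processed_meat_item03,processed_meat
fish_item01,fish
fish_item02,fish
fish_item03,fish
shellfish_item01,shellfish
shellfish_item02,shellfish
shellfish_item03,shellfish
eggs_item01,eggs
eggs_item02,eggs
eggs_item03,eggs
eggs_item04,eggs
dairy_item01,dairy
dairy_item02,dairy
dairy_item03,dairy
dairy_item04,dairy
oils_fats_item01,oils_fats
oils_fats_item02,oils_fats
oils_fats_item03,oils_fats
oils_fats_item04,oils_fats
sweets_item01,sweets
sweets_item02,sweets
sweets_item03,sweets
coffee_tea_item01,coffee_tea
coffee_tea_item02,coffee_tea
coffee_tea_item03,coffee_tea
coffee_tea_item04,coffee_tea
soups_stews_item01,soups_stews
soups_stews_item02,soups_stews
soups_stews_item03,soups_stews
soups_stews_item04,soups_stews
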