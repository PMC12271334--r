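keyword,group
rice,staples
noodle,staples
porridge,staples
congee,staples
bread,staples
bun,staples
mantou,staples
dumpling,staples
wonton,staples
pancake,staples
potato,staples
corn,staples
millet,staples
oat,staples
vermicelli,staples
vegetable,vegetables
greens,vegetables
cabbage,vegetables
spinach,vegetables
broccoli,vegetables
celery,vegetables
cucumber,vegetables
tomato,vegetables
eggplant,vegetables
pepper,vegetables
mushroom,vegetables
radish,vegetables
carrot,vegetables
pumpkin,vegetables
gourd,vegetables
lettuce,vegetables
onion,vegetables
leek,vegetables
bamboo,vegetables
apple,fruits
banana,fruits
orange,fruits
pear,fruits
grape,fruits
peach,fruits
watermelon,fruits
kiwi,fruits
cherry,fruits
strawberry,fruits
pomelo,fruits
fruit,fruits
pork,animal_foods
beef,animal_foods
lamb,animal_foods
mutton,animal_foods
chicken,animal_foods
duck,animal_foods
fish,animal_foods
shrimp,animal_foods
crab,animal_foods
egg,animal_foods
meat,animal_foods
ham,animal_foods
sausage,animal_foods
milk,dairy
yogurt,dairy
yoghurt,dairy
cheese,dairy
tofu,legumes_nuts_seeds
soy,legumes_nuts_seeds
bean,legumes_nuts_seeds
peanut,legumes_nuts_seeds
walnut,legumes_nuts_seeds
almond,legumes_nuts_seeds
nut,legumes_nuts_seeds
sesame,legumes_nuts_seeds
lentil,legumes_nuts_seeds
chickpea,legumes_nuts_seeds
candy,sweets
chocolate,sweets
cake,sweets
cookie,sweets
biscuit,sweets
sugar,sweets
honey,sweets
ice cream,sweets
pastry,sweets
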