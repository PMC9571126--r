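{
  "questions": [
    {"id": "bread",             "label": "Bread",               "portion_unit": "portions/day"},
    {"id": "pasta",             "label": "Pasta",               "portion_unit": "portions/day"},
    {"id": "breakfast_cereals", "label": "Breakfast cereals",   "portion_unit": "portions/day"},
    {"id": "baked_sweets",      "label": "Baked sweets",        "portion_unit": "portions/day"},
    {"id": "potatoes",          "label": "Potatoes",            "portion_unit": "portions/day"},
    {"id": "fruit",             "label": "Fruit",               "portion_unit": "portions/day"},
    {"id": "vegetables",        "label": "Vegetables",          "portion_unit": "portions/day"},
    {"id": "red_meat",          "label": "Red meat",            "portion_unit": "portions/day"},
    {"id": "white_meat",        "label": "White meat",          "portion_unit": "portions/day"},
    {"id": "fish",              "label": "Fish",                "portion_unit": "portions/day"},
    {"id": "conserved_fish",    "label": "Conserved fish",      "portion_unit": "portions/day"},
    {"id": "eggs",              "label": "Eggs",                "portion_unit": "portions/day"},
    {"id": "lentils",           "label": "Lentils and legumes", "portion_unit": "portions/day"},
    {"id": "milk_yoghurt",      "label": "Milk / yoghurt",      "portion_unit": "portions/day"},
    {"id": "cheese",            "label": "Cheese",              "portion_unit": "portions/day"},
    {"id": "olive_oil",         "label": "Olive oil",           "portion_unit": "portions/day"},
    {"id": "other_oils_butter", "label": "Other oils / butter", "portion_unit": "portions/day"},
    {"id": "dried_fruit",       "label": "Dried fruit",         "portion_unit": "portions/day"},
    {"id": "water",             "label": "Water",               "portion_unit": "portions/day"},
    {"id": "processed_meat",    "label": "Processed meat",      "portion_unit": "portions/day"},
    {"id": "sweets_snacks",     "label": "Sweets / snacks",     "portion_unit": "portions/day"},
    {"id": "sugar",             "label": "Sugar",               "portion_unit": "portions/day"},
    {"id": "honey_marmalade",   "label": "Honey / marmalade",   "portion_unit": "portions/day"},
    {"id": "sweet_drinks",      "label": "Sweet drinks",        "portion_unit": "portions/day"}
  ],
  "goals": [
    {"id": "fruit_vegetables", "label": "Fruit and vegetables", "threshold": 5.0, "direction": "at_least",
     "questions": ["fruit", "vegetables"]},
    {"id": "carbohydrates",    "label": "Carbohydrates",        "threshold": 4.0, "direction": "at_most",
     "questions": ["bread", "pasta", "breakfast_cereals", "potatoes"]},
    {"id": "proteins",         "label": "Proteins",             "threshold": 2.0, "direction": "at_most",
     "questions": ["red_meat", "white_meat", "fish", "conserved_fish", "eggs", "lentils"]},
    {"id": "milk",             "label": "Milk and dairy",       "threshold": 2.0, "direction": "at_most",
     "questions": ["milk_yoghurt", "cheese"]},
    {"id": "oil",              "label": "Olive oil",            "threshold": 2.0, "direction": "at_least",
     "questions": ["olive_oil"]},
    {"id": "water",            "label": "Water",                "threshold": 6.0, "direction": "at_least",
     "questions": ["water"]},
    {"id": "dried_fruit",      "label": "Dried fruit",          "threshold": 1.0, "direction": "at_least",
     "questions": ["dried_fruit"]},
    {"id": "processed_meats",  "label": "Processed meats",      "threshold": 0.5, "direction": "at_most",
     "questions": ["processed_meat"]},
    {"id": "sweets_snacks",    "label": "Sweets and snacks",    "threshold": 1.0, "direction": "at_most",
     "questions": ["baked_sweets", "sweets_snacks"]},
    {"id": "sweet_drinks",     "label": "Sweet drinks",         "threshold": 0.5, "direction": "at_most",
     "questions": ["sweet_drinks"]},
    {"id": "sugar",            "label": "Sugar",                "threshold": 2.0, "direction": "at_most",
     "questions": ["sugar", "honey_marmalade"]}
  ]
}
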