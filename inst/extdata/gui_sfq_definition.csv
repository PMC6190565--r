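group_code,label,polarity,include_keywords,exclude_keywords
C25a,Fresh fruit,healthy,fresh fruit;fruit;banana;apple;pear;orange;grapes,juice;juices
C25b,Cooked vegetables,healthy,cooked vegetables;carrots;peas;broccoli;turnip,raw
C25c,Raw vegetables or salad,healthy,raw vegetables;salad;lettuce;cucumber;tomato,cooked
C25d,"Full fat cheese, yogurt or fromage frais",healthy,full fat cheese;full fat yogurt;fromage frais;cheese;cheddar cheese;yogurt,low;cream
C25e,Low fat cheese or low fat yogurt,healthy,low fat cheese;low fat yogurt,full
C25f,Full cream milk or full cream milk products,healthy,full cream milk;whole milk;milk,skimmed;semi
C25g,Skimmed or semi-skimmed milk or milk products,healthy,skimmed milk;semi skimmed milk,full;whole
C25h,"Water (tap, still or sparkling)",healthy,water;tap water;still water;sparkling water,
C25i,"Hamburger, hot dog, sausage or meat pie",unhealthy,hamburger;hot dog;sausage;sausages;meat pie,chips;fries
C25j,Hot chips or French fries,unhealthy,hot chips;french fries;chips;fries;potato wedges,dog
C25k,Crisps or savoury snacks,unhealthy,crisps;savoury snacks;popcorn,
C25l,"Biscuits, doughnuts, cake, pie or chocolate",unhealthy,biscuits;doughnuts;cake;chocolate;sponge cake;muffins,
C25m,Sweets,unhealthy,sweets;jellies;lollipops;candy,
C25n,"Fizzy drinks, minerals, cordial or squash (diet)",unhealthy,diet cola;diet lemonade;diet cordial,
C25o,"Fizzy drinks, minerals, cordial or squash (not diet)",unhealthy,fizzy drinks;minerals;squash,diet
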